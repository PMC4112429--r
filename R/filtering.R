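#' Flag variants as rare / novel from reference-panel frequencies
#'
#' The frequency used is the maximum over all panels; a panel in which
#' the variant was not observed contributes 0. A variant is *rare* when
#' that maximum is strictly below `rare_threshold` and *novel* when it
#' is 0 in every panel, so the novel set is always a subset of the rare
#' set.
#'
#' @param freq Numeric vector of panel frequencies for one variant, or
#'   a numeric matrix/data.frame with one row per variant and one
#'   column per panel. `NA` means unobserved.
#' @param rare_threshold Rarity threshold, a fraction in (0,1);
#'   default 0.005 (0.5%).
#' @return data.frame with logical columns `is_rare`, `is_novel`
#'   (one row per variant).
#' @export
flag_frequency <- function(freq, rare_threshold = 0.005) {
  stopifnot(is.numeric(rare_threshold), length(rare_threshold) == 1L,
            rare_threshold > 0, rare_threshold < 1)
  if (is.data.frame(freq)) freq <- as.matrix(freq)
  if (!is.matrix(freq)) freq <- matrix(freq, nrow = 1L)
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0,1]", call. = FALSE)
  freq[is.na(freq)] <- 0
  fmax <- if (ncol(freq)) apply(freq, 1L, max) else
    rep(0, nrow(freq))
  data.frame(is_rare = fmax < rare_threshold, is_novel = fmax == 0)
}

#' Flag functional consequence classes
#'
#' @param consequence Character vector of consequence classes (see
#'   [consequence_classes()]).
#' @return Logical vector: `TRUE` for missense, stop gain/loss,
#'   frameshift indels and splice-site variants.
#' @export
flag_functional <- function(consequence) {
  bad <- setdiff(consequence, consequence_classes())
  if (length(bad))
    stop("unrecognised consequence class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  consequence %in% functional_classes()
}

#' Annotate a cohort's variant table with filter flags
#'
#' @param cohort An [fh_cohort()].
#' @param rare_threshold Passed to [flag_frequency()].
#' @return The cohort's variant table with logical columns `is_rare`,
#'   `is_novel`, `is_functional` appended.
#' @export
flag_variants <- function(cohort, rare_threshold = 0.005) {
  v <- cohort$variants
  fr <- flag_frequency(v[cohort$freq_panels], rare_threshold)
  v$is_rare <- fr$is_rare
  v$is_novel <- fr$is_novel
  v$is_functional <- flag_functional(v$consequence)
  v
}

#' Count qualifying carrier events per gene in cases and controls
#'
#' Applies the variant-class predicate (novel-and-functional by
#' default, or rare-and-functional) and counts carrier events — one
#' per (sample, variant) call passing the predicate — gene by gene in
#' each group. Genes with no qualifying call in either group are
#' absent from the result. Variant lists are preserved for reporting.
#'
#' @param cohort An [fh_cohort()].
#' @param variant_class `"novel"` (panel frequency 0) or `"rare"`
#'   (panel frequency < `rare_threshold`).
#' @param functional_only Restrict to functional consequence classes
#'   (default `TRUE`).
#' @param rare_threshold Rarity threshold, see [flag_frequency()].
#' @param cases Optional subset of case sample ids to count (the
#'   pipeline passes the post-exclusion case set); defaults to all
#'   cases.
#' @return data.frame with one row per gene: `gene`, `chrom`,
#'   `k_case`, `k_control`, `case_variants`, `control_variants`
#'   (`;`-separated key lists, one entry per carrier event).
#' @export
collect_gene_counts <- function(cohort,
                                variant_class = c("novel", "rare"),
                                functional_only = TRUE,
                                rare_threshold = 0.005,
                                cases = NULL) {
  variant_class <- match.arg(variant_class)
  if (is.null(cases)) cases <- cohort$cases
  stopifnot(all(cases %in% cohort$cases))
  v <- flag_variants(cohort, rare_threshold)
  keep <- if (variant_class == "novel") v$is_novel else v$is_rare
  if (functional_only) keep <- keep & v$is_functional
  keep <- keep & !is.na(v$gene)
  v <- v[keep, , drop = FALSE]
  calls <- cohort$calls[cohort$calls$key %in% v$key, , drop = FALSE]
  calls <- calls[calls$sample_id %in% c(cases, cohort$controls), ,
                 drop = FALSE]
  empty <- data.frame(gene = character(), chrom = character(),
                      k_case = integer(), k_control = integer(),
                      case_variants = character(),
                      control_variants = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  m <- match(calls$key, v$key)
  calls$gene <- v$gene[m]
  calls$chrom <- v$chrom[m]
  calls$group <- ifelse(calls$sample_id %in% cases, "case", "control")
  out <- lapply(split(calls, calls$gene), function(g) {
    data.frame(gene = g$gene[1L], chrom = g$chrom[1L],
               k_case = sum(g$group == "case"),
               k_control = sum(g$group == "control"),
               case_variants = paste(sort(g$key[g$group == "case"]),
                                     collapse = ";"),
               control_variants = paste(sort(g$key[g$group == "control"]),
                                        collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}
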