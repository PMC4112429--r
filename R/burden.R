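#' One-sided exact binomial burden p-value for a gene
#'
#' Pools the qualifying carrier events of one gene across both groups
#' and asks how surprising the case share is: with
#' `n = k_case + k_control` events and success probability
#' `pi = n_case / (n_case + n_control)` (the case fraction of the
#' cohort), the p-value is the upper binomial tail
#' `P(X >= k_case)`. With no case events (or no events at all) the
#' p-value is 1.
#'
#' @param k_case,k_control Qualifying carrier-event counts in cases
#'   and controls (vectorized).
#' @param n_case,n_control Numbers of case and control samples.
#' @return Numeric p-values in (0, 1].
#' @examples
#' binomial_burden_p(3, 2, 71, 1926)  # ~4.3e-4
#' @export
binomial_burden_p <- function(k_case, k_control, n_case, n_control) {
  if (any(k_case < 0) || any(k_control < 0))
    stop("carrier-event counts must be non-negative", call. = FALSE)
  if (n_case <= 0 || n_control <= 0)
    stop("cohort sizes must be positive", call. = FALSE)
  pi <- n_case / (n_case + n_control)
  n <- k_case + k_control
  p <- pbinom(k_case - 1, n, pi, lower.tail = FALSE)
  p[k_case == 0 | n == 0] <- 1
  pmin(p, 1)
}

#' Run the gene-by-gene burden scan with the discovery filters
#'
#' Applies, per gene: exclusion of configured chromosomes (X by
#' default, plus Y and mitochondrial labels), exclusion of genes with
#' more than `max_control_variants` qualifying control events (a gene
#' that common in controls is unlikely to harbour a dominant FH
#' mutation), exclusion of genes with no case events, and the exact
#' binomial test on the remainder. A gene is flagged when its p-value
#' is strictly below `p_flag_threshold`. A Bonferroni-adjusted column
#' over the tested genes is emitted for information only; the flag
#' itself is uncorrected, as a follow-up trigger rather than a claim
#' of exome-wide significance.
#'
#' @param counts Per-gene counts from [collect_gene_counts()].
#' @param n_case,n_control Cohort sizes.
#' @param max_control_variants Keep genes with at most this many
#'   control events (default 4; "more than four" are excluded).
#' @param p_flag_threshold Flagging threshold (default 4e-3, strict).
#' @param exclude_chroms Chromosome labels to exclude.
#' @return data.frame, one row per gene, sorted by ascending p then
#'   gene (excluded genes last): `gene`, `chrom`, `k_case`,
#'   `k_control`, `p_value`, `p_bonferroni`, `status`, `flagged`,
#'   `case_variants`, `control_variants`.
#' @export
run_burden_scan <- function(counts, n_case, n_control,
                            max_control_variants = 4,
                            p_flag_threshold = 4e-3,
                            exclude_chroms = c("X", "chrX", "Y", "chrY",
                                               "MT", "chrM", "M")) {
  res <- counts[c("gene", "chrom", "k_case", "k_control",
                  "case_variants", "control_variants")]
  res$status <- "tested"
  res$status[res$k_case == 0] <- "excluded_no_variants"
  res$status[res$k_control > max_control_variants] <-
    "excluded_control_count"
  res$status[res$chrom %in% exclude_chroms] <- "excluded_x_chromosome"
  res$p_value <- NA_real_
  tested <- res$status == "tested"
  res$p_value[tested] <- binomial_burden_p(res$k_case[tested],
                                           res$k_control[tested],
                                           n_case, n_control)
  res$p_bonferroni <- pmin(res$p_value * sum(tested), 1)
  res$flagged <- !is.na(res$p_value) & res$p_value < p_flag_threshold
  res <- res[order(!tested, res$p_value, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res[c("gene", "chrom", "k_case", "k_control", "p_value",
        "p_bonferroni", "status", "flagged", "case_variants",
        "control_variants")]
}

#' Burden test over a configured gene list (Tier-2 / linkage loci)
#'
#' Tests the listed genes as one pooled group (counts summed over all
#' listed genes, single binomial test) and gene by gene. Unlike the
#' whole-exome scan, no control-count or chromosome filters are
#' applied: the candidate list is tested as given. Listed genes with
#' no qualifying events contribute zero counts.
#'
#' @param counts Per-gene counts from [collect_gene_counts()].
#' @param gene_list Non-empty character vector of gene symbols.
#' @param n_case,n_control Cohort sizes.
#' @param p_flag_threshold Flagging threshold (default 4e-3).
#' @return List with `combined` (one-row data.frame for the pooled
#'   test) and `per_gene` (data.frame as in [run_burden_scan()],
#'   without exclusions).
#' @export
run_gene_list_burden <- function(counts, gene_list, n_case, n_control,
                                 p_flag_threshold = 4e-3) {
  if (length(gene_list) == 0L)
    stop("gene_list must be non-empty", call. = FALSE)
  sub <- counts[counts$gene %in% gene_list, , drop = FALSE]
  missing <- setdiff(gene_list, sub$gene)
  if (length(missing)) {
    sub <- rbind(sub, data.frame(gene = missing, chrom = NA_character_,
                                 k_case = 0L, k_control = 0L,
                                 case_variants = "",
                                 control_variants = "",
                                 stringsAsFactors = FALSE))
  }
  kc <- sum(sub$k_case); kn <- sum(sub$k_control)
  combined <- data.frame(
    genes = paste(sort(gene_list), collapse = ";"),
    k_case = kc, k_control = kn,
    p_value = binomial_burden_p(kc, kn, n_case, n_control),
    stringsAsFactors = FALSE)
  combined$flagged <- combined$p_value < p_flag_threshold
  per_gene <- sub
  per_gene$status <- "tested"
  per_gene$p_value <- binomial_burden_p(per_gene$k_case,
                                        per_gene$k_control,
                                        n_case, n_control)
  per_gene$p_bonferroni <- pmin(per_gene$p_value * nrow(per_gene), 1)
  per_gene$flagged <- per_gene$p_value < p_flag_threshold
  per_gene <- per_gene[order(per_gene$p_value, per_gene$gene), ,
                       drop = FALSE]
  rownames(per_gene) <- NULL
  list(combined = combined,
       per_gene = per_gene[c("gene", "chrom", "k_case", "k_control",
                             "p_value", "p_bonferroni", "status",
                             "flagged", "case_variants",
                             "control_variants")])
}

#' Expected number of affected carriers in a control cohort
#'
#' With a disease prevalence of 1/500, a cohort of 1926 unscreened
#' controls is expected to contain about 4 affected carriers — the
#' rationale behind tolerating up to 4 qualifying control events per
#' gene.
#'
#' @param n_controls Cohort size.
#' @param prevalence Disease prevalence in (0, 1).
#' @return List with `expected` (`n * prevalence`) and `rounded`
#'   (nearest integer).
#' @examples
#' expected_carriers(1926, 1/500)
#' @export
expected_carriers <- function(n_controls, prevalence) {
  stopifnot(n_controls >= 0)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0,1)", call. = FALSE)
  e <- n_controls * prevalence
  list(expected = e, rounded = round(e))
}

#' Allele frequency from an allele count in diploid individuals
#'
#' @param allele_count Observed allele count (0 to `2 * n_individuals`).
#' @param n_individuals Number of diploid individuals.
#' @return Frequency `allele_count / (2 * n_individuals)`.
#' @examples
#' maf_from_count(1, 6503)  # ~0.00008
#' @export
maf_from_count <- function(allele_count, n_individuals) {
  if (any(n_individuals <= 0))
    stop("n_individuals must be positive", call. = FALSE)
  if (any(allele_count < 0) || any(allele_count > 2 * n_individuals))
    stop("allele_count must lie in [0, 2 * n_individuals]",
         call. = FALSE)
  allele_count / (2 * n_individuals)
}
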