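apoe_table <- c(e2e2 = -0.9, e2e3 = -0.4, e2e4 = -0.2,
                e3e3 = 0, e3e4 = 0.1, e4e4 = 0.2)

normalize_apoe <- function(genotype) {
  g <- tolower(as.character(genotype))
  vapply(g, function(x) {
    if (is.na(x)) return(NA_character_)
    hits <- regmatches(x, gregexpr("e[234]", x))[[1]]
    if (length(hits) != 2L)
      stop("invalid APOE genotype: '", x,
           "' (expected a pair from e2/e3/e4)", call. = FALSE)
    paste(sort(hits), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Score an APOE haplotype pair
#'
#' Fixed lookup of the APOE diplotype term of the LDL-C gene score:
#' e2e2 = -0.9, e2e3 = -0.4, e2e4 = -0.2, e3e3 = 0, e3e4 = 0.1,
#' e4e4 = 0.2. The pair is unordered (`"e4e2"` scores as `"e2e4"`).
#'
#' @param genotype Character vector of diplotypes, e.g. `"e2e3"`,
#'   `"e3/e3"`, `"E4E2"`; `NA` propagates.
#' @return Numeric score values.
#' @examples
#' apoe_score(c("e2e2", "e3e3", "e4e2"))
#' @export
apoe_score <- function(genotype) {
  unname(apoe_table[normalize_apoe(genotype)])
}

#' Derive the APOE diplotype from rs429358 and rs7412 genotypes
#'
#' Standard haplotype construction: on (rs429358, rs7412) a T;T
#' haplotype is e2, T;C is e3 and C;C is e4. With unphased genotypes
#' the e4 count is the number of C alleles at rs429358 and the e2
#' count the number of T alleles at rs7412; the ambiguous double
#' heterozygote therefore resolves to e2/e4, the only phase consistent
#' with no e1 allele. A genotype pair implying an e1 haplotype
#' (rs429358-C with rs7412-T in excess) is returned as `NA`, as is any
#' missing genotype.
#'
#' @param rs429358,rs7412 Character vectors of genotypes such as
#'   `"T/T"`, `"C/T"` or `"CT"`.
#' @return Character vector of diplotypes (`"e2e4"` style) or `NA`
#'   where the haplotype is unavailable.
#' @examples
#' apoe_from_snps("T/T", "C/C")  # e3e3
#' apoe_from_snps("C/T", "C/T")  # e2e4
#' @export
apoe_from_snps <- function(rs429358, rs7412) {
  parse_gt <- function(g, snp) {
    a <- strsplit(gsub("[/|]", "", toupper(as.character(g))), "",
                  fixed = TRUE)
    vapply(seq_along(a), function(i) {
      x <- a[[i]]
      if (any(is.na(x)) || length(x) != 2L) return(NA_integer_)
      if (!all(x %in% c("C", "T")))
        stop("invalid ", snp, " genotype: '", g[i], "'", call. = FALSE)
      sum(x == if (snp == "rs429358") "C" else "T")
    }, integer(1))
  }
  n4 <- parse_gt(rs429358, "rs429358")  # C alleles -> e4
  n2 <- parse_gt(rs7412, "rs7412")      # T alleles -> e2
  out <- rep(NA_character_, length(n4))
  ok <- !is.na(n4) & !is.na(n2) & (n4 + n2) <= 2L
  n3 <- 2L - n4 - n2
  hap <- function(i) paste(sort(rep(c("e2", "e3", "e4"),
                                    c(n2[i], n3[i], n4[i]))),
                           collapse = "")
  out[ok] <- vapply(which(ok), hap, character(1))
  out
}

#' Read a SNP weight table
#'
#' TSV with header; columns `snp_id`, `effect_allele`, `other_allele`,
#' `weight` (optionally `chrom`, `pos`, `provenance`). Weights are in
#' LDL-C score units per effect allele.
#'
#' @param path Path to the TSV file.
#' @return data.frame of validated weights.
#' @export
read_snp_weights <- function(path) {
  w <- read.delim(path, stringsAsFactors = FALSE)
  validate_snp_weights(w)
}

validate_snp_weights <- function(w) {
  need <- c("snp_id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(w)))
    stop("weight table missing column(s): ",
         paste(setdiff(need, names(w)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(w$snp_id))
    stop("duplicate snp_id in weight table", call. = FALSE)
  if (!all(w$effect_allele %in% c("A", "C", "G", "T")) ||
      !all(w$other_allele %in% c("A", "C", "G", "T")))
    stop("alleles must be A/C/G/T", call. = FALSE)
  if (any(!is.finite(w$weight)))
    stop("weights must be finite", call. = FALSE)
  w
}

#' Read a long-format genotype table
#'
#' TSV with header; columns `sample_id`, `snp_id`, `allele1`,
#' `allele2`. Missing genotypes are empty or `NA` alleles.
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_genotypes <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "snp_id", "allele1", "allele2")
  if (!all(need %in% names(g)))
    stop("genotype table missing column(s): ",
         paste(setdiff(need, names(g)), collapse = ", "), call. = FALSE)
  g
}

#' Compute the weighted LDL-C gene score per sample
#'
#' The SNP component is the sum over the score SNPs of
#' `weight * dosage`, where dosage counts effect alleles (0, 1 or 2);
#' the APOE component is the diplotype table value
#' (see [apoe_score()]). A sample is *complete* — and scoreable — only
#' when every SNP in the weight table and the APOE diplotype are
#' genotyped; otherwise its total is `NA` and it is later classified
#' `unscored` rather than imputed.
#'
#' @param genotypes Long-format genotype table (`sample_id`, `snp_id`,
#'   `allele1`, `allele2`). May include `rs429358`/`rs7412` rows used
#'   to derive APOE when `apoe` is not supplied.
#' @param weights SNP weight table (see [read_snp_weights()]).
#' @param apoe Optional data.frame `sample_id`, `apoe` (diplotype
#'   strings, e.g. `"e3e4"`). When `NULL`, APOE is derived from
#'   rs429358/rs7412 genotype rows.
#' @return data.frame, one row per sample: `sample_id`,
#'   `snp_component`, `apoe_component`, `total`, `n_snps_typed`,
#'   `complete`.
#' @export
gene_score <- function(genotypes, weights, apoe = NULL) {
  weights <- validate_snp_weights(weights)
  samples <- unique(c(genotypes$sample_id,
                      if (!is.null(apoe)) apoe$sample_id))
  # APOE component
  if (is.null(apoe)) {
    get_snp <- function(id) {
      g <- genotypes[genotypes$snp_id == id, , drop = FALSE]
      gt <- rep(NA_character_, length(samples))
      m <- match(samples, g$sample_id)
      ok <- !is.na(m) & !is.na(g$allele1[m]) & !is.na(g$allele2[m])
      gt[ok] <- paste0(g$allele1[m][ok], g$allele2[m][ok])
      gt
    }
    hap <- apoe_from_snps(get_snp("rs429358"), get_snp("rs7412"))
  } else {
    hap <- normalize_apoe(apoe$apoe[match(samples, apoe$sample_id)])
  }
  apoe_component <- unname(apoe_table[hap])
  # SNP component
  g <- genotypes[genotypes$snp_id %in% weights$snp_id, , drop = FALSE]
  wi <- match(g$snp_id, weights$snp_id)
  eff <- weights$effect_allele[wi]
  oth <- weights$other_allele[wi]
  a1 <- toupper(g$allele1); a2 <- toupper(g$allele2)
  typed <- !is.na(a1) & !is.na(a2)
  bad <- typed & !(a1 %in% c("A", "C", "G", "T") & (a1 == eff | a1 == oth) &
                     a2 %in% c("A", "C", "G", "T") & (a2 == eff | a2 == oth))
  if (any(bad))
    stop("genotype allele(s) not matching effect/other pair for SNP ",
         paste(unique(g$snp_id[bad]), collapse = ", "), call. = FALSE)
  dosage <- ifelse(typed, (a1 == eff) + (a2 == eff), NA_integer_)
  contrib <- weights$weight[wi] * dosage
  si <- match(g$sample_id, samples)
  snp_component <- rep(0, length(samples))
  n_typed <- integer(length(samples))
  for (i in seq_along(si)) {
    if (!is.na(contrib[i])) {
      snp_component[si[i]] <- snp_component[si[i]] + contrib[i]
      n_typed[si[i]] <- n_typed[si[i]] + 1L
    }
  }
  complete <- n_typed == nrow(weights) & !is.na(apoe_component)
  data.frame(sample_id = samples,
             snp_component = ifelse(n_typed == nrow(weights),
                                    snp_component, NA_real_),
             apoe_component = apoe_component,
             total = ifelse(complete, snp_component + apoe_component,
                            NA_real_),
             n_snps_typed = n_typed,
             complete = complete,
             stringsAsFactors = FALSE)
}

#' Classify polygenic hypercholesterolaemia by score cutoff
#'
#' A complete score strictly above the cutoff (the healthy-population
#' top-decile boundary, 1.16 by default; 1.08 is the 9th-decile
#' alternative) is classified `polygenic`; a complete score at or
#' below it `not_polygenic`; an incomplete score is always `unscored`.
#'
#' @param scores Result of [gene_score()].
#' @param cutoff Score cutoff (default 1.16).
#' @return `scores` with a `classification` column appended.
#' @export
classify_polygenic <- function(scores, cutoff = 1.16) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  scores$classification <- ifelse(
    !scores$complete, "unscored",
    ifelse(scores$total > cutoff, "polygenic", "not_polygenic"))
  scores
}

#' Compare gene-score distributions between groups
#'
#' Pairwise Welch two-sample t tests (unequal variance) and a one-way
#' ANOVA across all groups, as used to compare healthy controls with
#' mutation-positive and mutation-negative FH patients. Comparisons
#' involving a group with fewer than two values are marked
#' not-computable (`NA`).
#'
#' @param scores Named list of numeric score vectors, one per group
#'   (`NA`s dropped).
#' @return List with `groups` (summary data.frame), `pairwise`
#'   (data.frame `group1`, `group2`, `t`, `p`) and `anova_p`.
#' @export
compare_groups <- function(scores) {
  stopifnot(is.list(scores), length(names(scores)) == length(scores))
  scores <- lapply(scores, function(x) x[!is.na(x)])
  nonempty <- names(scores)[vapply(scores, length, integer(1)) > 0L]
  if (length(nonempty) < 2L)
    stop("need at least two non-empty groups", call. = FALSE)
  groups <- data.frame(
    group = names(scores),
    n = vapply(scores, length, integer(1)),
    mean = vapply(scores, function(x) if (length(x)) mean(x) else NA_real_,
                  numeric(1)),
    sd = vapply(scores, function(x) if (length(x) > 1L) sd(x) else NA_real_,
                numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  cmb <- utils::combn(names(scores), 2L)
  pairwise <- data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ],
                         t = NA_real_, p = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb))) {
    x <- scores[[cmb[1L, i]]]; y <- scores[[cmb[2L, i]]]
    if (length(x) >= 2L && length(y) >= 2L &&
        (sd(x) > 0 || sd(y) > 0)) {
      tt <- t.test(x, y, var.equal = FALSE)
      pairwise$t[i] <- unname(tt$statistic)
      pairwise$p[i] <- tt$p.value
    }
  }
  long <- data.frame(
    score = unlist(scores, use.names = FALSE),
    group = rep(names(scores), vapply(scores, length, integer(1))))
  anova_p <- NA_real_
  if (length(unique(long$group)) >= 2L &&
      all(table(long$group) >= 1L) && sd(long$score) > 0) {
    a <- anova(lm(score ~ group, data = long))
    anova_p <- a[["Pr(>F)"]][1L]
  }
  list(groups = groups, pairwise = pairwise, anova_p = anova_p)
}
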