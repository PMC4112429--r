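#' Default synthetic gene panel for cohort simulation
#'
#' A deterministic panel of autosomal genes with per-gene background
#' rates of a qualifying (novel functional) carrier event per sample.
#' Rates are log-spaced between 5e-5 and 2e-3, so an average gene
#' carries on the order of one qualifying control event in a cohort of
#' ~2000 — the regime in which the burden test operates.
#'
#' @param n_genes Number of genes (default 500).
#' @return data.frame with columns `gene`, `chrom`, `rate`.
#' @export
default_gene_panel <- function(n_genes = 500) {
  data.frame(gene = sprintf("G%04d", seq_len(n_genes)),
             chrom = as.character(rep(1:22, length.out = n_genes)),
             rate = exp(seq(log(5e-5), log(2e-3),
                            length.out = n_genes)),
             stringsAsFactors = FALSE)
}

#' Synthetic stand-in catalogue of known FH mutations
#'
#' A small Tier-1 catalogue for simulation and testing. The APOB
#' p.(Arg3527Gln) and PCSK9 p.(Asp374Tyr) entries use their well-known
#' coordinates; the LDLR and LDLRAP1 entries are synthetic
#' placeholders. This is not a clinical resource: real screening
#' requires a curated mutation database supplied by the user.
#'
#' @return Catalogue data.frame with normalized `key` column (see
#'   [validate_catalogue()]).
#' @export
synthetic_tier1_catalogue <- function() {
  cat_df <- data.frame(
    gene = c("LDLR", "LDLR", "LDLR", "LDLR", "APOB", "PCSK9",
             "LDLRAP1", "APOB"),
    chrom = c("19", "19", "19", "19", "2", "1", "1", "2"),
    pos = c(11216230L, 11217315L, 11218100L, 11221440L, 21229160L,
            55518316L, 25870520L, 21230600L),
    ref = c("C", "G", "TACA", "C", "C", "G", "T", "G"),
    alt = c("T", "A", "T", "A", "T", "T", "TA", "A"),
    hgvs_c = c("c.1060C>T", "c.1432G>A", "c.2140_2142del", "c.2054C>A",
               "c.10580G>A", "c.1120G>T", "c.432_433insA", "c.148G>A"),
    pathogenicity = c("known_fh", "known_fh", "known_fh", "known_fh",
                      "known_fh", "known_fh", "known_fh",
                      "unknown_effect"),
    stringsAsFactors = FALSE)
  validate_catalogue(cat_df)
}

#' Default synthetic LDL-C score model
#'
#' Twelve independent score SNPs with placeholder identifiers, effect
#' alleles, effect-allele frequencies and weights, plus APOE haplotype
#' frequencies. Weights carry a `provenance = "synthetic"` marker: the
#' published GWAS-consortium weights are not redistributed here and
#' real analyses must supply them. The weight scale is chosen in
#' closed form so that the analytic mean score of an unselected
#' population is `target_mean` (0.90); with the chosen frequency
#' spread the simulated 90th percentile falls at ~1.16, the top-decile
#' cutoff used for polygenic classification.
#'
#' @param target_mean Analytic population mean score (default 0.90).
#' @return List with `snps` (data.frame: `snp_id`, `effect_allele`,
#'   `other_allele`, `freq`, `weight`, `provenance`), `apoe_freqs`
#'   (named haplotype frequencies), and `target_mean`.
#' @export
default_score_model <- function(target_mean = 0.90) {
  freq <- c(0.724, 0.340, 0.604, 0.156, 0.700, 0.804, 0.212, 0.756,
            0.380, 0.812, 0.460, 0.660)
  w0 <- c(0.15, 0.10, 0.07, 0.06, 0.06, 0.05, 0.05, 0.04, 0.04,
          0.18, 0.03, 0.04)
  apoe_freqs <- c(e2 = 0.08, e3 = 0.77, e4 = 0.15)
  haps <- names(apoe_freqs)
  pair_key <- outer(haps, haps, function(a, b)
    paste0(pmin(a, b), pmax(a, b)))
  apoe_mean <- sum(outer(apoe_freqs, apoe_freqs) * apoe_table[pair_key])
  scale <- (target_mean - apoe_mean) / sum(2 * w0 * freq)
  snps <- data.frame(
    snp_id = sprintf("ldl_snp%02d", seq_along(freq)),
    effect_allele = "A", other_allele = "G",
    freq = freq, weight = scale * w0,
    provenance = "synthetic",
    stringsAsFactors = FALSE)
  list(snps = snps, apoe_freqs = apoe_freqs, target_mean = target_mean)
}

#' Build a simulation configuration
#'
#' Defines the cohort the generator emulates: 125 cases against 1926
#' controls, a gene panel with per-gene background rates of novel
#' functional carrier events, optional case-enrichment multipliers,
#' Tier-1 mutations spiked into a subset of cases, and an LDL-C score
#' model with a planted fraction of polygenic (high-score) cases among
#' the mutation-negatives.
#'
#' @param seed Mandatory integer seed; the whole simulation is
#'   reproducible from it.
#' @param n_cases,n_controls Cohort sizes (defaults 125 and 1926).
#' @param genes Gene panel data.frame (`gene`, `chrom`, `rate`).
#' @param enrichment Named numeric vector of case rate multipliers
#'   (gene -> multiplier >= 0); genes not named have multiplier 1.
#' @param catalogue Tier-1 catalogue used for spiking (validated).
#' @param n_tier1 Number of cases spiked with a dominant known
#'   mutation (default 25).
#' @param tier1_high_overlap Number of spiked cases that additionally
#'   receive a high (above-cutoff) score (default 2).
#' @param polygenic_fraction Fraction of mutation-negative cases
#'   planted with an above-cutoff score (default 0.29).
#' @param score_cutoff Polygenic cutoff the planting conditions on
#'   (default 1.16).
#' @param score_model Score model from [default_score_model()], or
#'   `NULL` to skip genotype generation entirely.
#' @param score_missing_fraction Fraction of cases rendered unscorable
#'   by dropping one SNP genotype (default 16/125, applied only to
#'   cases not planted high so planted counts stay exact).
#' @param common_missense_rate,novel_synonymous_rate Per-sample
#'   per-gene rates of non-qualifying background calls (a common
#'   missense variant and a novel synonymous variant), exercising the
#'   frequency and consequence filters downstream.
#' @return An object of class `fh_sim_config`.
#' @export
sim_config <- function(seed,
                       n_cases = 125, n_controls = 1926,
                       genes = default_gene_panel(),
                       enrichment = NULL,
                       catalogue = synthetic_tier1_catalogue(),
                       n_tier1 = 25,
                       tier1_high_overlap = 2,
                       polygenic_fraction = 0.29,
                       score_cutoff = 1.16,
                       score_model = default_score_model(),
                       score_missing_fraction = 16 / 125,
                       common_missense_rate = 5e-4,
                       novel_synonymous_rate = 5e-4) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("a single integer seed is mandatory", call. = FALSE)
  stopifnot(n_cases >= 1, n_controls >= 1,
            all(c("gene", "chrom", "rate") %in% names(genes)),
            all(genes$rate >= 0 & genes$rate <= 1),
            polygenic_fraction >= 0, polygenic_fraction <= 1,
            score_missing_fraction >= 0, score_missing_fraction <= 1,
            n_tier1 >= 0, tier1_high_overlap >= 0,
            tier1_high_overlap <= n_tier1, n_tier1 <= n_cases)
  if (!is.null(enrichment)) {
    if (is.null(names(enrichment)) || any(enrichment < 0))
      stop("enrichment must be a named vector of multipliers >= 0",
           call. = FALSE)
    unknown <- setdiff(names(enrichment), genes$gene)
    if (length(unknown))
      stop("enrichment names not in the gene panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    mult <- enrichment[match(genes$gene, names(enrichment))]
    mult[is.na(mult)] <- 1
    if (any(genes$rate * mult > 1))
      stop("enriched case rate exceeds 1 for gene(s): ",
           paste(genes$gene[genes$rate * mult > 1], collapse = ", "),
           call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_cases = n_cases,
                 n_controls = n_controls, genes = genes,
                 enrichment = enrichment, catalogue = catalogue,
                 n_tier1 = n_tier1,
                 tier1_high_overlap = tier1_high_overlap,
                 polygenic_fraction = polygenic_fraction,
                 score_cutoff = score_cutoff,
                 score_model = score_model,
                 score_missing_fraction = score_missing_fraction,
                 common_missense_rate = common_missense_rate,
                 novel_synonymous_rate = novel_synonymous_rate),
            class = "fh_sim_config")
}

# draw n total scores from the score model; returns list(dosage matrix,
# apoe haplotypes, totals)
draw_scores <- function(model, n) {
  snps <- model$snps
  dosage <- vapply(snps$freq, function(f) rbinom(n, 2L, f),
                   integer(n))
  dosage <- matrix(dosage, nrow = n)
  haps <- names(model$apoe_freqs)
  h1 <- sample(haps, n, TRUE, model$apoe_freqs)
  h2 <- sample(haps, n, TRUE, model$apoe_freqs)
  apoe <- paste0(pmin(h1, h2), pmax(h1, h2))
  total <- as.vector(dosage %*% snps$weight) +
    unname(apoe_table[apoe])
  list(dosage = dosage, apoe = apoe, total = total)
}

# rejection-sample n scores conditional on total > cutoff (above=TRUE)
# or total <= cutoff (above=FALSE)
draw_scores_conditional <- function(model, n, cutoff, above) {
  out <- NULL
  while (is.null(out) || length(out$total) < n) {
    batch <- draw_scores(model, max(2L * n, 50L))
    keep <- if (above) batch$total > cutoff else batch$total <= cutoff
    if (!any(keep)) next
    sub <- list(dosage = batch$dosage[keep, , drop = FALSE],
                apoe = batch$apoe[keep], total = batch$total[keep])
    out <- if (is.null(out)) sub else
      list(dosage = rbind(out$dosage, sub$dosage),
           apoe = c(out$apoe, sub$apoe),
           total = c(out$total, sub$total))
  }
  list(dosage = out$dosage[seq_len(n), , drop = FALSE],
       apoe = out$apoe[seq_len(n)], total = out$total[seq_len(n)])
}

#' Simulate a case/control exome cohort with planted signals
#'
#' Generates, reproducibly from the seed in `config`:
#' * per (sample, gene), at most one qualifying novel functional
#'   carrier event with the gene's background rate (times the
#'   enrichment multiplier in cases), each event being a unique novel
#'   missense variant;
#' * non-qualifying background calls (common missense and novel
#'   synonymous) at low rates, so downstream filters have work to do;
#' * Tier-1 known mutations from the catalogue spiked into
#'   `n_tier1` cases;
#' * 12-SNP genotypes and APOE diplotypes for every sample, with the
#'   configured fraction of mutation-negative cases planted strictly
#'   above the score cutoff (and `tier1_high_overlap` spiked cases
#'   likewise), all other cases at or below it, and controls drawn
#'   unconditionally;
#' * a truth table recording every planted signal.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `fh_sim`: list with `cohort`
#'   ([fh_cohort()]), `genotypes` (long table or `NULL`), `apoe`
#'   (diplotype table or `NULL`), `truth` (list: `tier1_samples`,
#'   `planted_high`, `enriched_genes`), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "fh_sim_config"))
  set.seed(config$seed)
  cases <- sprintf("case%04d", seq_len(config$n_cases))
  controls <- sprintf("ctrl%04d", seq_len(config$n_controls))
  genes <- config$genes
  mult <- rep(1, nrow(genes))
  if (!is.null(config$enrichment)) {
    m <- match(names(config$enrichment), genes$gene)
    mult[m] <- config$enrichment
  }

  calls <- list()
  variants <- list()
  vid <- 0L
  add_variant <- function(chrom, pos, ref, alt, gene, consequence,
                          kg1000, esp6500, hgvs_c = "") {
    n <- length(chrom)
    data.frame(key = if (n) paste(chrom, pos, ref, alt, sep = ":")
               else character(),
               chrom = chrom, pos = pos, ref = rep_len(ref, n),
               alt = rep_len(alt, n), gene = rep_len(gene, n),
               transcript = rep_len("", n),
               hgvs_c = rep_len(hgvs_c, n),
               consequence = rep_len(consequence, n),
               kg1000 = rep_len(kg1000, n),
               esp6500 = rep_len(esp6500, n),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    r <- genes$rate[i]
    base_pos <- i * 100000L
    emit <- function(samples, offset0) {
      if (!length(samples)) return(NULL)
      pos <- base_pos + offset0 + seq_along(samples)
      list(variants = add_variant(genes$chrom[i], pos, "A", "G",
                                  genes$gene[i], "missense", 0, 0),
           calls = data.frame(sample_id = samples,
                              key = paste(genes$chrom[i], pos, "A", "G",
                                          sep = ":"),
                              zygosity = "het",
                              stringsAsFactors = FALSE))
    }
    k_ca <- rbinom(1L, config$n_cases, min(1, r * mult[i]))
    k_co <- rbinom(1L, config$n_controls, r)
    ev <- list(
      emit(if (k_ca) sample(cases, k_ca) else character(), 0L),
      emit(if (k_co) sample(controls, k_co) else character(), 1000L))
    # non-qualifying background: one common missense and one novel
    # synonymous site per gene, carried at low rates
    if (config$common_missense_rate > 0) {
      k <- rbinom(1L, config$n_cases + config$n_controls,
                  config$common_missense_rate)
      if (k) {
        carriers <- sample(c(cases, controls), k)
        pos <- base_pos + 5000L
        ev <- c(ev, list(list(
          variants = add_variant(genes$chrom[i], pos, "C", "T",
                                 genes$gene[i], "missense", 0.02, 0.03),
          calls = data.frame(sample_id = carriers,
                             key = paste(genes$chrom[i], pos, "C", "T",
                                         sep = ":"),
                             zygosity = "het",
                             stringsAsFactors = FALSE))))
      }
    }
    if (config$novel_synonymous_rate > 0) {
      k <- rbinom(1L, config$n_cases + config$n_controls,
                  config$novel_synonymous_rate)
      if (k) {
        carriers <- sample(c(cases, controls), k)
        pos <- base_pos + 6000L
        ev <- c(ev, list(list(
          variants = add_variant(genes$chrom[i], pos, "G", "A",
                                 genes$gene[i], "synonymous", 0, 0),
          calls = data.frame(sample_id = carriers,
                             key = paste(genes$chrom[i], pos, "G", "A",
                                         sep = ":"),
                             zygosity = "het",
                             stringsAsFactors = FALSE))))
      }
    }
    ev <- ev[!vapply(ev, is.null, logical(1))]
    if (length(ev)) {
      vid <- vid + 1L
      variants[[vid]] <- do.call(rbind, lapply(ev, `[[`, "variants"))
      calls[[vid]] <- do.call(rbind, lapply(ev, `[[`, "calls"))
    }
  }

  # Tier-1 spike: dominant known_fh catalogue entries into n_tier1 cases
  spikeable <- config$catalogue[
    config$catalogue$pathogenicity == "known_fh" &
      config$catalogue$gene != "LDLRAP1", , drop = FALSE]
  tier1_samples <- data.frame(sample_id = character(),
                              key = character(), gene = character(),
                              stringsAsFactors = FALSE)
  if (config$n_tier1 > 0) {
    if (!nrow(spikeable))
      stop("no dominant known_fh catalogue entries to spike",
           call. = FALSE)
    picked <- sample(cases, config$n_tier1)
    entry <- spikeable[rep_len(seq_len(nrow(spikeable)),
                               config$n_tier1), , drop = FALSE]
    tier1_samples <- data.frame(sample_id = picked, key = entry$key,
                                gene = entry$gene,
                                stringsAsFactors = FALSE)
    vid <- vid + 1L
    uniq <- entry[!duplicated(entry$key), , drop = FALSE]
    norm <- normalize_variant(uniq$chrom, uniq$pos, uniq$ref, uniq$alt)
    variants[[vid]] <- add_variant(norm$chrom, norm$pos, norm$ref,
                                   norm$alt, uniq$gene, "missense",
                                   0, 0, hgvs_c = uniq$hgvs_c)
    calls[[vid]] <- data.frame(sample_id = picked, key = entry$key,
                               zygosity = "het",
                               stringsAsFactors = FALSE)
  }

  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), key = character(),
               zygosity = character(), stringsAsFactors = FALSE)
  variants <- if (length(variants)) do.call(rbind, variants) else
    add_variant(character(), integer(), character(), character(),
                character(), character(), numeric(), numeric())
  variants <- variants[!duplicated(variants$key), , drop = FALSE]
  calls <- calls[!duplicated(calls[c("sample_id", "key")]), ,
                 drop = FALSE]
  cohort <- fh_cohort(cases, controls, calls, variants,
                      freq_panels = c("kg1000", "esp6500"))

  # score genotypes
  genotypes <- NULL; apoe <- NULL
  planted_high <- character()
  if (!is.null(config$score_model)) {
    model <- config$score_model
    negatives <- setdiff(cases, tier1_samples$sample_id)
    n_poly <- round(config$polygenic_fraction * length(negatives))
    planted_high <- c(
      if (n_poly) sample(negatives, n_poly) else character(),
      if (config$tier1_high_overlap)
        sample(unique(tier1_samples$sample_id),
               config$tier1_high_overlap) else character())
    low_cases <- setdiff(cases, planted_high)
    parts <- list(
      list(ids = planted_high,
           draw = draw_scores_conditional(model, length(planted_high),
                                          config$score_cutoff, TRUE)),
      list(ids = low_cases,
           draw = draw_scores_conditional(model, length(low_cases),
                                          config$score_cutoff, FALSE)),
      list(ids = controls, draw = draw_scores(model, length(controls))))
    ids <- unlist(lapply(parts, `[[`, "ids"))
    dosage <- do.call(rbind, lapply(parts, function(p) p$draw$dosage))
    apoe <- data.frame(
      sample_id = ids,
      apoe = unlist(lapply(parts, function(p) p$draw$apoe)),
      stringsAsFactors = FALSE)
    snps <- model$snps
    genotypes <- data.frame(
      sample_id = rep(ids, each = nrow(snps)),
      snp_id = rep(snps$snp_id, length(ids)),
      allele1 = ifelse(as.vector(t(dosage)) >= 1L,
                       rep(snps$effect_allele, length(ids)),
                       rep(snps$other_allele, length(ids))),
      allele2 = ifelse(as.vector(t(dosage)) == 2L,
                       rep(snps$effect_allele, length(ids)),
                       rep(snps$other_allele, length(ids))),
      stringsAsFactors = FALSE)
    # render a fraction of non-planted cases unscorable
    n_missing <- round(config$score_missing_fraction * config$n_cases)
    pool <- intersect(low_cases, cases)
    n_missing <- min(n_missing, length(pool))
    if (n_missing > 0) {
      drop_samples <- sample(pool, n_missing)
      drop_snp <- sample(snps$snp_id, n_missing, replace = TRUE)
      idx <- match(paste(drop_samples, drop_snp),
                   paste(genotypes$sample_id, genotypes$snp_id))
      genotypes$allele1[idx] <- NA
      genotypes$allele2[idx] <- NA
    }
  }

  enriched_genes <- if (is.null(config$enrichment)) character() else
    names(config$enrichment)[config$enrichment > 1]
  structure(list(cohort = cohort, genotypes = genotypes, apoe = apoe,
                 truth = list(tier1_samples = tier1_samples,
                              planted_high = planted_high,
                              enriched_genes = enriched_genes),
                 config = config),
            class = "fh_sim")
}

#' @export
print.fh_sim <- function(x, ...) {
  cat("fh_sim: ", case_n(x$cohort), " cases / ", control_n(x$cohort),
      " controls, ", nrow(x$cohort$calls), " calls\n", sep = "")
  cat("  planted: ", nrow(x$truth$tier1_samples), " tier1 carriers, ",
      length(x$truth$planted_high), " high-score samples, ",
      length(x$truth$enriched_genes), " enriched gene(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to the pipeline's input formats
#'
#' Emits case and control VCFs, the annotation TSV, the catalogue,
#' genotype/APOE tables and the truth table into a directory, so a
#' simulated study can be run through the file-based entry points.
#'
#' @param sim An `fh_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cases = file.path(dir, "cases.vcf"),
             controls = file.path(dir, "controls.vcf"),
             annotation = file.path(dir, "annotation.tsv"),
             catalogue = file.path(dir, "catalogue.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             apoe = file.path(dir, "apoe.tsv"),
             truth_tier1 = file.path(dir, "truth_tier1.tsv"),
             truth_high = file.path(dir, "truth_planted_high.tsv"))
  write_cohort(sim$cohort, paths["cases"], paths["controls"],
               paths["annotation"])
  cat_df <- sim$config$catalogue
  write.table(cat_df[setdiff(names(cat_df), "key")],
              paths["catalogue"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sim$genotypes))
    write.table(sim$genotypes, paths["genotypes"], sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(sim$apoe))
    write.table(sim$apoe, paths["apoe"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  write.table(sim$truth$tier1_samples, paths["truth_tier1"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = sim$truth$planted_high),
              paths["truth_high"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Recover planted simulation parameters with the package's own tools
#'
#' Runs the Tier-1 screen, the score classification and the burden
#' scan on a simulated cohort and compares the results with the truth
#' table: Tier-1 recall on spiked mutations, polygenic classification
#' sensitivity/specificity and the recovered polygenic case fraction,
#' the control top-decile property, and burden-scan power (planted
#' enriched genes flagged) and type-I error (null panel genes
#' flagged).
#'
#' @param sim An `fh_sim` object.
#' @return List of recovery metrics (see details above), plus the
#'   underlying `scan`, `screen` and `scores` objects.
#' @export
recover_parameters <- function(sim) {
  config <- sim$config
  cohort <- sim$cohort
  truth <- sim$truth

  screen <- screen_tier1(cohort, config$catalogue)
  planted <- unique(truth$tier1_samples$sample_id)
  tier1_recall <- if (length(planted))
    mean(planted %in% screen$explained) else NA_real_

  poly <- list(sensitivity = NA_real_, specificity = NA_real_,
               planted_fraction = NA_real_,
               recovered_fraction = NA_real_,
               control_decile_fraction = NA_real_,
               empirical_control_q90 = NA_real_)
  scores <- NULL
  if (!is.null(sim$genotypes)) {
    scores <- classify_polygenic(
      gene_score(sim$genotypes, config$score_model$snps, sim$apoe),
      cutoff = config$score_cutoff)
    negatives <- setdiff(cohort$cases, planted)
    cls <- scores$classification[match(negatives, scores$sample_id)]
    ph_neg <- intersect(truth$planted_high, negatives)
    poly$planted_fraction <- length(ph_neg) / length(negatives)
    poly$recovered_fraction <- mean(cls == "polygenic")
    if (length(truth$planted_high))
      poly$sensitivity <- mean(
        scores$classification[match(truth$planted_high,
                                    scores$sample_id)] == "polygenic")
    not_planted <- setdiff(cohort$cases, truth$planted_high)
    np_cls <- scores$classification[match(not_planted,
                                          scores$sample_id)]
    poly$specificity <- mean(np_cls[np_cls != "unscored"] !=
                               "polygenic")
    ctrl_tot <- scores$total[match(cohort$controls,
                                   scores$sample_id)]
    ctrl_tot <- ctrl_tot[!is.na(ctrl_tot)]
    q90 <- quantile(ctrl_tot, 0.9, names = FALSE, type = 7)
    poly$empirical_control_q90 <- q90
    poly$control_decile_fraction <- mean(ctrl_tot > q90)
  }

  counts <- collect_gene_counts(cohort, "novel")
  scan <- run_burden_scan(counts, case_n(cohort), control_n(cohort))
  panel_genes <- config$genes$gene
  enriched <- intersect(truth$enriched_genes, panel_genes)
  null_genes <- setdiff(panel_genes, enriched)
  flagged <- scan$gene[scan$flagged]
  power <- if (length(enriched))
    mean(enriched %in% flagged) else NA_real_
  type1 <- mean(null_genes %in% flagged)

  c(list(tier1_recall = tier1_recall,
         tier1_found = sum(planted %in% screen$explained),
         tier1_planted = length(planted),
         burden_power = power, burden_type1 = type1),
    poly,
    list(scan = scan, screen = screen, scores = scores))
}

#' Flagged-gene fraction of null burden scans
#'
#' Repeatedly simulates a cohort with no planted signal (all
#' multipliers 1, no spikes, no score model), runs the burden scan,
#' and records the fraction of panel genes flagged at the threshold.
#' Used to demonstrate that the discrete test is valid/conservative:
#' the mean flagged fraction should not exceed the nominal level.
#'
#' @param n_reps Number of replicate scans.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param n_cases,n_controls Cohort sizes (defaults 71 and 1926, the
#'   post-exclusion comparison).
#' @param genes Gene panel.
#' @param p_flag_threshold Flagging threshold (default 4e-3).
#' @return Numeric vector of per-replicate flagged fractions
#'   (denominator: all panel genes).
#' @export
null_scan_fractions <- function(n_reps, seed, n_cases = 71,
                                n_controls = 1926,
                                genes = default_gene_panel(500),
                                p_flag_threshold = 4e-3) {
  vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(seed = seed + r, n_cases = n_cases,
                      n_controls = n_controls, genes = genes,
                      n_tier1 = 0, tier1_high_overlap = 0,
                      polygenic_fraction = 0, score_model = NULL,
                      common_missense_rate = 0,
                      novel_synonymous_rate = 0)
    sim <- simulate_cohort(cfg)
    counts <- collect_gene_counts(sim$cohort, "novel")
    scan <- run_burden_scan(counts, n_cases, n_controls,
                            p_flag_threshold = p_flag_threshold)
    sum(scan$flagged) / nrow(genes)
  }, numeric(1))
}
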