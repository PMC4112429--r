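#' Run the full gene-discovery cascade
#'
#' Orchestrates the discovery pipeline in order: Tier-1 known-mutation
#' screen, LDL-C gene-score triage of the mutation-negative samples,
#' exclusion of explained samples (Tier-1 carriers and polygenic
#' high-score samples; a sample that is both counts once, under
#' Tier-1), qualifying-variant filtering, and the gene-by-gene burden
#' scan of the remaining cases against all controls. Samples with no
#' attainable gene score are never excluded as polygenic. The run is
#' deterministic given its inputs.
#'
#' @param cohort An [fh_cohort()].
#' @param catalogue Known-mutation catalogue
#'   (see [read_mutation_catalogue()]).
#' @param genotypes Long-format score-SNP genotype table, or `NULL`
#'   to skip score triage.
#' @param weights SNP weight table (required when `genotypes` given).
#' @param apoe Optional APOE diplotype table (`sample_id`, `apoe`).
#' @param score_cutoff Polygenic classification cutoff (default 1.16).
#' @param variant_class,rare_threshold Qualifying-variant predicate,
#'   see [collect_gene_counts()].
#' @param max_control_variants,p_flag_threshold,exclude_chroms Burden
#'   scan settings, see [run_burden_scan()].
#' @return An object of class `fh_report`: list with
#'   `n_total_cases`, `n_tier1_excluded`, `n_polygenic_excluded`,
#'   `n_remaining`, `remaining_cases`, `burden`, `triage`, `scores`,
#'   `tier1_matches`, `log`.
#' @export
run_pipeline <- function(cohort, catalogue, genotypes = NULL,
                         weights = NULL, apoe = NULL,
                         score_cutoff = 1.16,
                         variant_class = c("novel", "rare"),
                         rare_threshold = 0.005,
                         max_control_variants = 4,
                         p_flag_threshold = 4e-3,
                         exclude_chroms = c("X", "chrX", "Y", "chrY",
                                            "MT", "chrM", "M")) {
  variant_class <- match.arg(variant_class)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  note("cohort: ", case_n(cohort), " cases, ", control_n(cohort),
       " controls")
  screen <- stage("tier1", screen_tier1(cohort, catalogue))
  note("tier1 screen: ", nrow(screen$matches), " catalogue match(es), ",
       length(screen$explained), " sample(s) explained")

  scores <- NULL
  if (!is.null(genotypes)) {
    if (is.null(weights))
      stop("pipeline stage 'genescore' failed: genotypes supplied ",
           "without a weight table", call. = FALSE)
    scores <- stage("genescore", {
      s <- gene_score(genotypes, weights, apoe)
      classify_polygenic(s, cutoff = score_cutoff)
    })
    note("gene score: ", sum(scores$complete), " of ",
         nrow(scores), " genotyped sample(s) scored; ",
         sum(scores$classification == "polygenic"),
         " above cutoff ", score_cutoff)
  }
  triage <- stage("triage",
                  triage_samples(cohort$cases, screen, scores))
  tier1_excluded <- triage$sample_id[triage$status == "tier1_mutation"]
  poly_excluded <- triage$sample_id[triage$status == "polygenic"]
  remaining <- setdiff(cohort$cases, c(tier1_excluded, poly_excluded))
  note("exclusions: ", length(tier1_excluded), " tier1 carrier(s), ",
       length(poly_excluded),
       " polygenic mutation-negative sample(s); ",
       length(remaining), " case(s) remain")

  counts <- stage("filtering",
                  collect_gene_counts(cohort, variant_class,
                                      functional_only = TRUE,
                                      rare_threshold = rare_threshold,
                                      cases = remaining))
  note("filtering: ", nrow(counts), " gene(s) with one or more ",
       "qualifying (", variant_class, " functional) carrier event")
  burden <- stage("burden",
                  run_burden_scan(counts, length(remaining),
                                  control_n(cohort),
                                  max_control_variants,
                                  p_flag_threshold, exclude_chroms))
  note("burden scan: ", sum(burden$status == "tested"),
       " gene(s) tested, ", sum(burden$flagged), " flagged at p < ",
       p_flag_threshold)

  report <- structure(list(
    n_total_cases = case_n(cohort),
    n_tier1_excluded = length(tier1_excluded),
    n_polygenic_excluded = length(poly_excluded),
    n_remaining = length(remaining),
    remaining_cases = sort(remaining),
    burden = burden, triage = triage, scores = scores,
    tier1_matches = screen$matches, log = log), class = "fh_report")
  stopifnot(report$n_remaining ==
              report$n_total_cases - report$n_tier1_excluded -
              report$n_polygenic_excluded)
  report
}

#' @export
print.fh_report <- function(x, ...) {
  cat("FH gene-discovery report\n")
  cat("  cases: ", x$n_total_cases, " total; ", x$n_tier1_excluded,
      " Tier-1 excluded; ", x$n_polygenic_excluded,
      " polygenic excluded; ", x$n_remaining, " remaining\n", sep = "")
  flagged <- x$burden[x$burden$flagged, , drop = FALSE]
  cat("  burden: ", sum(x$burden$status == "tested"), " genes tested, ",
      nrow(flagged), " flagged\n", sep = "")
  if (nrow(flagged)) {
    top <- utils::head(flagged, 10L)
    cat(sprintf("    %-12s %-5s %3s %3s  %s\n", "gene", "chr", "kca",
                "kco", "p"))
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-12s %-5s %3d %3d  %.2g\n", top$gene[i],
                  top$chrom[i], top$k_case[i], top$k_control[i],
                  top$p_value[i]))
  }
  invisible(x)
}

#' Run the pipeline from a YAML configuration file
#'
#' The configuration names every input and threshold:
#' ```yaml
#' case_vcfs: [cases.vcf]
#' control_vcfs: [controls.vcf]
#' annotation: annotation.tsv
#' catalogue: catalogue.tsv
#' genotypes: genotypes.tsv      # optional
#' weights: weights.tsv          # required with genotypes
#' apoe: apoe.tsv                # optional (sample_id, apoe)
#' score_cutoff: 1.16
#' variant_class: novel
#' rare_threshold: 0.005
#' max_control_variants: 4
#' p_flag_threshold: 0.004
#' ```
#'
#' @param config_path Path to the YAML file; relative input paths are
#'   resolved against its directory.
#' @return An `fh_report`, see [run_pipeline()].
#' @export
run_pipeline_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  rel <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  cohort <- read_cohort(rel(unlist(cfg$case_vcfs)),
                        rel(unlist(cfg$control_vcfs)),
                        rel(cfg$annotation))
  catalogue <- read_mutation_catalogue(rel(cfg$catalogue))
  genotypes <- if (!is.null(cfg$genotypes)) read_genotypes(rel(cfg$genotypes))
  weights <- if (!is.null(cfg$weights)) read_snp_weights(rel(cfg$weights))
  apoe <- if (!is.null(cfg$apoe))
    read.delim(rel(cfg$apoe), stringsAsFactors = FALSE)
  args <- list(cohort = cohort, catalogue = catalogue,
               genotypes = genotypes, weights = weights, apoe = apoe)
  for (k in c("score_cutoff", "variant_class", "rare_threshold",
              "max_control_variants", "p_flag_threshold"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  do.call(run_pipeline, args)
}

#' Write the burden table of a report to TSV
#'
#' Mirrors the published table layout: gene, chromosome, case and
#' control carrier-event counts, p-value (full precision plus a
#' 2-significant-figure display column), status, flag, and the
#' qualifying variant lists.
#'
#' @param report An `fh_report`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_burden_table <- function(report, path) {
  b <- report$burden
  b$p_display <- signif(b$p_value, 2)
  write.table(b[c("gene", "chrom", "k_case", "k_control", "p_display",
                  "p_value", "p_bonferroni", "status", "flagged",
                  "case_variants", "control_variants")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
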