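default_tier1_genes <- c("LDLR", "APOB", "PCSK9", "LDLRAP1")

#' Read a known-FH-mutation catalogue
#'
#' Tab-separated with header; columns `gene`, `chrom`, `pos`, `ref`,
#' `alt`, `hgvs_c`, `pathogenicity` (`known_fh` or `unknown_effect`).
#' Coordinates are normalized with [normalize_variant()] on load so
#' that matching is representation-independent. An entry in a gene
#' outside the Tier-1 set is a configuration error.
#'
#' @param path Path to the TSV file.
#' @param tier1_genes Allowed gene symbols (default LDLR, APOB, PCSK9,
#'   LDLRAP1).
#' @return data.frame with a normalized `key` column.
#' @export
read_mutation_catalogue <- function(path,
                                    tier1_genes = default_tier1_genes) {
  if (!file.exists(path))
    stop("cannot read mutation catalogue: ", path, call. = FALSE)
  cat_df <- read.delim(path, stringsAsFactors = FALSE,
                       colClasses = c(chrom = "character"))
  need <- c("gene", "chrom", "pos", "ref", "alt", "hgvs_c",
            "pathogenicity")
  if (!all(need %in% names(cat_df)))
    stop("catalogue missing column(s): ",
         paste(setdiff(need, names(cat_df)), collapse = ", "),
         call. = FALSE)
  validate_catalogue(cat_df, tier1_genes)
}

#' Validate an in-memory mutation catalogue
#'
#' @param cat_df data.frame with columns `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `hgvs_c`, `pathogenicity`.
#' @inheritParams read_mutation_catalogue
#' @return The catalogue with a normalized `key` column added.
#' @export
validate_catalogue <- function(cat_df,
                               tier1_genes = default_tier1_genes) {
  bad <- setdiff(unique(cat_df$gene), tier1_genes)
  if (length(bad))
    stop("catalogue entries in non-Tier-1 gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!all(cat_df$pathogenicity %in% c("known_fh", "unknown_effect")))
    stop("pathogenicity must be 'known_fh' or 'unknown_effect'",
         call. = FALSE)
  cat_df$key <- variant_key(cat_df$chrom, cat_df$pos, cat_df$ref,
                            cat_df$alt)
  cat_df
}

#' Read a plain-text gene list
#'
#' One gene symbol per line; blank lines and `#` comments ignored.
#' Used for Tier-1/Tier-2 gene sets and linkage-locus candidate lists.
#'
#' @param path Path to the text file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path))
    stop("cannot read gene list: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Screen samples against the known-mutation catalogue
#'
#' A call matches a catalogue entry when its normalized variant key is
#' equal, or — as a fallback for entries whose coordinates drift
#' between annotation sources — when its HGVS coding string is equal.
#' A sample is *explained* (Tier-1 mutation carrier) when it matches a
#' `known_fh` entry in a dominant-model gene, or, in recessive-model
#' genes (LDLRAP1 by default), when it is homozygous for one such
#' entry or carries two or more distinct heterozygous matches in the
#' gene. A single heterozygous match in a recessive gene is reported
#' but does not explain the phenotype. `unknown_effect` entries are
#' reported, never explanatory.
#'
#' @param cohort An [fh_cohort()].
#' @param catalogue Catalogue data.frame from
#'   [read_mutation_catalogue()] / [validate_catalogue()].
#' @param samples Sample ids to screen (default: the cases).
#' @param recessive_genes Genes requiring two hits (default
#'   `"LDLRAP1"`).
#' @return List with `matches` (data.frame: `sample_id`, `gene`,
#'   `key`, `hgvs_c`, `pathogenicity`, `zygosity`, `explains`) and
#'   `explained` (character vector of explained sample ids).
#' @export
screen_tier1 <- function(cohort, catalogue,
                         samples = cohort$cases,
                         recessive_genes = "LDLRAP1") {
  if (!nrow(catalogue)) {
    return(list(matches = data.frame(sample_id = character(),
                                     gene = character(),
                                     key = character(),
                                     hgvs_c = character(),
                                     pathogenicity = character(),
                                     zygosity = character(),
                                     explains = logical(),
                                     stringsAsFactors = FALSE),
                explained = character()))
  }
  calls <- cohort$calls[cohort$calls$sample_id %in% samples, ,
                        drop = FALSE]
  v <- cohort$variants
  mi <- match(calls$key, catalogue$key)
  # HGVS fallback for calls not matched by coordinate key
  hg <- v$hgvs_c[match(calls$key, v$key)]
  fallback <- is.na(mi) & !is.na(hg) & nzchar(hg) &
    hg %in% catalogue$hgvs_c[nzchar(catalogue$hgvs_c)]
  mi[fallback] <- match(hg[fallback], catalogue$hgvs_c)
  hit <- !is.na(mi)
  matches <- data.frame(sample_id = calls$sample_id[hit],
                        gene = catalogue$gene[mi[hit]],
                        key = catalogue$key[mi[hit]],
                        hgvs_c = catalogue$hgvs_c[mi[hit]],
                        pathogenicity = catalogue$pathogenicity[mi[hit]],
                        zygosity = calls$zygosity[hit],
                        stringsAsFactors = FALSE)
  matches <- matches[order(matches$sample_id, matches$gene,
                           matches$key), , drop = FALSE]
  rownames(matches) <- NULL
  explains <- logical(nrow(matches))
  if (nrow(matches)) {
    known <- matches$pathogenicity == "known_fh"
    dominant <- !(matches$gene %in% recessive_genes)
    explains[known & dominant] <- TRUE
    # recessive model: hom, or >= 2 distinct het hits in the gene
    rec <- which(known & !dominant)
    if (length(rec)) {
      grp <- paste(matches$sample_id[rec], matches$gene[rec])
      for (g in unique(grp)) {
        idx <- rec[grp == g]
        if (any(matches$zygosity[idx] == "hom") ||
            length(unique(matches$key[idx])) >= 2L)
          explains[idx] <- TRUE
      }
    }
  }
  matches$explains <- explains
  list(matches = matches,
       explained = sort(unique(matches$sample_id[matches$explains])))
}

#' Triage samples into tier1_mutation / polygenic / unexplained
#'
#' Combines the Tier-1 screen with polygenic-score classification.
#' A Tier-1 mutation takes precedence over a high polygenic score;
#' samples without an attainable score stay `unexplained` unless
#' Tier-1 explained.
#'
#' @param samples Character vector of sample ids to triage.
#' @param screen Result of [screen_tier1()].
#' @param scores Optional classified score table from
#'   [classify_polygenic()] (columns `sample_id`, `total`,
#'   `classification`).
#' @return data.frame: `sample_id`, `status`, `evidence`.
#' @export
triage_samples <- function(samples, screen, scores = NULL) {
  status <- rep("unexplained", length(samples))
  evidence <- rep(NA_character_, length(samples))
  if (!is.null(scores)) {
    m <- match(samples, scores$sample_id)
    poly <- !is.na(m) & scores$classification[m] == "polygenic"
    status[poly] <- "polygenic"
    evidence[poly] <- sprintf("gene score %.3f", scores$total[m][poly])
  }
  t1 <- samples %in% screen$explained
  status[t1] <- "tier1_mutation"
  ev <- vapply(samples[t1], function(s) {
    k <- screen$matches$key[screen$matches$sample_id == s &
                              screen$matches$explains]
    paste(unique(k), collapse = ";")
  }, character(1))
  evidence[t1] <- ev
  data.frame(sample_id = samples, status = status, evidence = evidence,
             stringsAsFactors = FALSE)
}
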