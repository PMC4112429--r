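#' Recognised variant consequence classes
#'
#' The enumerated consequence vocabulary used throughout the package.
#' The first six classes are the "functional" set: consequences that
#' plausibly alter the protein product (non-synonymous, stop gain/loss,
#' frameshift insertion/deletion, splice site).
#'
#' @return Character vector of the nine consequence class labels.
#' @export
consequence_classes <- function() {
  c("missense", "stop_gain", "stop_loss", "frameshift_ins",
    "frameshift_del", "splice_site", "synonymous", "intronic", "other")
}

#' Consequence classes counted as functional
#' @return Character vector (subset of [consequence_classes()]).
#' @export
functional_classes <- function() {
  c("missense", "stop_gain", "stop_loss", "frameshift_ins",
    "frameshift_del", "splice_site")
}

#' Normalize a variant to a canonical representation
#'
#' Trims the shared suffix, then the shared prefix (advancing the
#' position), so that padded representations of the same event collapse
#' to one key. SNVs are fixed points. Coordinates are 1-based, as in
#' VCF. A record whose alleles are identical after trimming is not a
#' variant and is rejected.
#'
#' @param chrom Chromosome label(s).
#' @param pos 1-based position(s).
#' @param ref,alt Non-empty allele strings.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `key` (the canonical `chrom:pos:ref:alt` string), one row per
#'   input variant.
#' @examples
#' normalize_variant("2", 21229160, "C", "T")$key
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("variant positions must be integers >= 1", call. = FALSE)
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("ref and alt alleles must be non-empty", call. = FALSE)
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    # trim shared suffix, keeping at least one base of each allele
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # trim shared prefix, advancing pos
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  bad <- ref == alt
  if (any(bad))
    stop("ref == alt after trimming (not a variant): ",
         paste(unique(paste0(chrom[bad], ":", pos[bad], ":", ref[bad])),
               collapse = ", "), call. = FALSE)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             key = paste(chrom, pos, ref, alt, sep = ":"),
             stringsAsFactors = FALSE)
}

#' Canonical variant key
#'
#' Convenience wrapper around [normalize_variant()] returning only the
#' `chrom:pos:ref:alt` key string.
#'
#' @inheritParams normalize_variant
#' @return Character vector of canonical keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  normalize_variant(chrom, pos, ref, alt)$key
}

variant_columns <- c("key", "chrom", "pos", "ref", "alt", "gene",
                     "transcript", "hgvs_c", "consequence")

#' Construct a case/control cohort dataset
#'
#' The in-memory container for a cohort: case and control sample ids,
#' one carrier-event record per (sample, variant) with zygosity, and a
#' variant table carrying gene, consequence class and reference-panel
#' allele frequencies.
#'
#' @param cases,controls Character vectors of sample ids (disjoint).
#' @param calls data.frame with columns `sample_id`, `key`, `zygosity`
#'   (`"het"` or `"hom"`); at most one row per (sample, key).
#' @param variants data.frame with columns `key`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `transcript`, `hgvs_c`, `consequence`, plus
#'   one numeric column per reference frequency panel.
#' @param freq_panels Character vector naming the frequency-panel
#'   columns of `variants`; defaults to all columns after the fixed
#'   ones.
#' @return An object of class `fh_cohort`: a list with elements
#'   `cases`, `controls`, `calls`, `variants`, `freq_panels`.
#' @export
fh_cohort <- function(cases, controls, calls, variants,
                      freq_panels = NULL) {
  cases <- unique(as.character(cases))
  controls <- unique(as.character(controls))
  overlap <- intersect(cases, controls)
  if (length(overlap))
    stop("sample id(s) appear in both cases and controls: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  stopifnot(is.data.frame(calls),
            all(c("sample_id", "key", "zygosity") %in% names(calls)))
  calls$sample_id <- as.character(calls$sample_id)
  if (!all(calls$zygosity %in% c("het", "hom")))
    stop("zygosity must be 'het' or 'hom'", call. = FALSE)
  unknown <- setdiff(calls$sample_id, c(cases, controls))
  if (length(unknown))
    stop("calls reference sample id(s) outside the cohort: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  if (anyDuplicated(calls[c("sample_id", "key")]))
    stop("duplicate (sample_id, key) call records", call. = FALSE)
  stopifnot(is.data.frame(variants),
            all(variant_columns %in% names(variants)))
  if (anyDuplicated(variants$key))
    stop("duplicate variant keys in variant table", call. = FALSE)
  if (!all(variants$consequence %in% consequence_classes()))
    stop("unrecognised consequence class(es): ",
         paste(setdiff(variants$consequence, consequence_classes()),
               collapse = ", "), call. = FALSE)
  if (is.null(freq_panels))
    freq_panels <- setdiff(names(variants), variant_columns)
  for (p in freq_panels) {
    variants[[p]] <- as.numeric(variants[[p]])
    f <- variants[[p]]
    if (any(!is.na(f) & (f < 0 | f > 1)))
      stop("frequencies in panel '", p, "' outside [0,1]", call. = FALSE)
  }
  missing_keys <- setdiff(calls$key, variants$key)
  if (length(missing_keys))
    stop("calls reference variant key(s) absent from the variant table: ",
         paste(utils::head(missing_keys, 5), collapse = ", "), call. = FALSE)
  structure(list(cases = cases, controls = controls,
                 calls = calls[order(calls$sample_id, calls$key), ,
                               drop = FALSE],
                 variants = variants, freq_panels = freq_panels),
            class = "fh_cohort")
}

#' @export
print.fh_cohort <- function(x, ...) {
  cat("fh_cohort: ", length(x$cases), " cases, ", length(x$controls),
      " controls\n", sep = "")
  cat("  ", nrow(x$variants), " variants, ", nrow(x$calls),
      " carrier events\n", sep = "")
  cat("  frequency panels: ",
      if (length(x$freq_panels)) paste(x$freq_panels, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Number of case / control samples
#' @param cohort An `fh_cohort`.
#' @return Integer count.
#' @export
case_n <- function(cohort) length(cohort$cases)

#' @rdname case_n
#' @export
control_n <- function(cohort) length(cohort$controls)

# Parse one VCF into per-sample decomposed calls.
# Returns list(samples = chr, calls = data.frame(sample_id, chrom, pos,
# ref, alt, zygosity)).
parse_vcf_calls <- function(path) {
  if (!file.exists(path))
    stop("cannot read VCF file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no genotype columns: ", path, call. = FALSE)
  samples <- colnames(gt)[-1L]
  fix <- v@fix
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alts <- alts[!is.na(alts) & alts != "."]
    if (!length(alts)) next
    gts <- sub(":.*$", "", gt[i, -1L])
    alleles <- strsplit(gts, "[/|]")
    rows <- list()
    for (ai in seq_along(alts)) {
      carried <- vapply(alleles, function(a) {
        a <- a[a != "." & !is.na(a)]
        sum(a == as.character(ai))
      }, integer(1), USE.NAMES = FALSE)
      ploidy <- vapply(alleles, function(a) sum(a != "." & !is.na(a)),
                       integer(1), USE.NAMES = FALSE)
      hit <- carried > 0L
      if (!any(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples[hit],
        chrom = unname(fix[i, "CHROM"]),
        pos = as.integer(fix[i, "POS"]),
        ref = unname(fix[i, "REF"]), alt = unname(alts[ai]),
        zygosity = ifelse(carried[hit] == ploidy[hit] & ploidy[hit] > 1L,
                          "hom", "het"),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) out[[i]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               zygosity = character(), stringsAsFactors = FALSE)
  list(samples = samples, calls = calls)
}

#' Read a variant annotation table
#'
#' Tab-separated, header required. Fixed columns `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `transcript`, `hgvs_c`, `consequence`; every
#' further column is interpreted as a reference frequency panel (e.g.
#' `kg1000`, `esp6500`) with allele frequencies in \[0,1\].
#'
#' @param path Path to the TSV file.
#' @return data.frame keyed by canonical variant key.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path))
    stop("cannot read annotation file: ", path, call. = FALSE)
  ann <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
            "hgvs_c", "consequence")
  if (!all(need %in% names(ann)))
    stop("annotation table missing column(s): ",
         paste(setdiff(need, names(ann)), collapse = ", "), call. = FALSE)
  norm <- normalize_variant(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann$chrom <- norm$chrom; ann$pos <- norm$pos
  ann$ref <- norm$ref; ann$alt <- norm$alt
  ann$key <- norm$key
  ann[c("key", need, setdiff(names(ann), c("key", need)))]
}

#' Read case and control VCFs into a cohort dataset
#'
#' Accepts one multi-sample VCF or several per-sample VCFs per group.
#' Every ALT allele with a non-reference genotype becomes one carrier
#' event; multi-allelic records are decomposed into one variant per
#' ALT; all variants are normalized with [normalize_variant()].
#' Variants absent from the annotation table are kept with consequence
#' `"other"` and no panel frequencies, and are reported via a message
#' and the `"unannotated"` attribute of the result.
#'
#' @param case_vcf_paths,control_vcf_paths Character vectors of VCF
#'   paths for case and control samples.
#' @param annotation_path Path to the annotation TSV
#'   (see [read_annotation()]).
#' @return An [fh_cohort()] object.
#' @export
read_cohort <- function(case_vcf_paths, control_vcf_paths,
                        annotation_path) {
  ann <- read_annotation(annotation_path)
  read_group <- function(paths) {
    parsed <- lapply(paths, parse_vcf_calls)
    samples <- unique(unlist(lapply(parsed, `[[`, "samples")))
    calls <- do.call(rbind, lapply(parsed, `[[`, "calls"))
    list(samples = samples, calls = calls)
  }
  ca <- read_group(case_vcf_paths)
  co <- read_group(control_vcf_paths)
  overlap <- intersect(ca$samples, co$samples)
  if (length(overlap))
    stop("sample id(s) present in both case and control inputs: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  calls <- rbind(ca$calls, co$calls)
  if (nrow(calls)) {
    norm <- normalize_variant(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls$key <- norm$key
    # collapse duplicate records of one event; hom wins over het
    calls <- calls[order(calls$sample_id, calls$key,
                         calls$zygosity != "hom"), ]
    calls <- calls[!duplicated(calls[c("sample_id", "key")]), ]
    uv <- norm[!duplicated(norm$key), , drop = FALSE]
  } else {
    calls$key <- character(0)
    uv <- data.frame(chrom = character(), pos = integer(),
                     ref = character(), alt = character(),
                     key = character(), stringsAsFactors = FALSE)
  }
  panels <- setdiff(names(ann), c("key", "chrom", "pos", "ref", "alt",
                                  "gene", "transcript", "hgvs_c",
                                  "consequence"))
  m <- match(uv$key, ann$key)
  variants <- data.frame(
    key = uv$key, chrom = uv$chrom, pos = uv$pos, ref = uv$ref,
    alt = uv$alt,
    gene = ifelse(is.na(m), NA_character_, ann$gene[m]),
    transcript = ifelse(is.na(m), NA_character_, ann$transcript[m]),
    hgvs_c = ifelse(is.na(m), NA_character_, ann$hgvs_c[m]),
    consequence = ifelse(is.na(m), "other", ann$consequence[m]),
    stringsAsFactors = FALSE)
  for (p in panels)
    variants[[p]] <- ifelse(is.na(m), NA_real_, ann[[p]][m])
  unannotated <- uv$key[is.na(m)]
  if (length(unannotated))
    message(length(unannotated),
            " variant(s) absent from the annotation table; kept with ",
            "consequence 'other' and no panel frequencies")
  cohort <- fh_cohort(ca$samples, co$samples,
                      calls[c("sample_id", "key", "zygosity")],
                      variants, freq_panels = panels)
  attr(cohort, "unannotated") <- unannotated
  cohort
}

#' Write a cohort back to VCF and annotation files
#'
#' Emits one multi-sample VCF per group (biallelic records, decomposed
#' representation) plus the annotation TSV, in the formats
#' [read_cohort()] consumes, so a cohort round-trips losslessly.
#'
#' @param cohort An `fh_cohort`.
#' @param case_path,control_path Output VCF paths.
#' @param annotation_path Output annotation TSV path.
#' @return Invisibly, the three paths.
#' @export
write_cohort <- function(cohort, case_path, control_path,
                         annotation_path) {
  write_group <- function(samples, path) {
    v <- cohort$variants
    v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
    calls <- cohort$calls[cohort$calls$sample_id %in% samples, ,
                          drop = FALSE]
    gt <- matrix("0/0", nrow = nrow(v), ncol = length(samples),
                 dimnames = list(NULL, samples))
    if (nrow(calls)) {
      ri <- match(calls$key, v$key)
      ci <- match(calls$sample_id, samples)
      gt[cbind(ri, ci)] <- ifelse(calls$zygosity == "hom", "1/1", "0/1")
    }
    lines <- c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"))
    if (nrow(v)) {
      body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                    ".", "GT", sep = "\t")
      body <- paste(body, apply(gt, 1, paste, collapse = "\t"),
                    sep = "\t")
      lines <- c(lines, body)
    }
    writeLines(lines, path)
  }
  write_group(cohort$cases, case_path)
  write_group(cohort$controls, control_path)
  ann <- cohort$variants[c("chrom", "pos", "ref", "alt", "gene",
                           "transcript", "hgvs_c", "consequence",
                           cohort$freq_panels)]
  write.table(ann, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(c(case_path, control_path, annotation_path))
}
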