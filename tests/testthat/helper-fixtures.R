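# Shared fixture builders and independent oracles.

# Independent brute-force oracle for the upper binomial tail:
# P(X >= k) with X ~ Binomial(n, pi), by direct term summation.
oracle_binom_tail <- function(k, n, pi) {
  if (k <= 0) return(1)
  if (n == 0) return(1)
  j <- k:n
  sum(choose(n, j) * pi^j * (1 - pi)^(n - j))
}

# Minimal variant table row(s).
make_variants <- function(chrom, pos, gene,
                          consequence = "missense",
                          kg1000 = 0, esp6500 = 0,
                          ref = "A", alt = "G",
                          hgvs_c = "") {
  n <- max(length(chrom), length(pos), length(gene),
           length(consequence), length(kg1000), length(esp6500))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n); ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  data.frame(key = paste(chrom, pos, ref, alt, sep = ":"),
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene = rep_len(gene, n), transcript = "",
             hgvs_c = rep_len(hgvs_c, n),
             consequence = rep_len(consequence, n),
             kg1000 = rep_len(kg1000, n),
             esp6500 = rep_len(esp6500, n),
             stringsAsFactors = FALSE)
}

make_calls <- function(sample_id, key, zygosity = "het") {
  data.frame(sample_id = sample_id, key = key,
             zygosity = rep_len(zygosity, length(sample_id)),
             stringsAsFactors = FALSE)
}

# A cohort echoing the published top-gene structure: one gene with 3
# qualifying case events and 2 control events, one synonymous-only
# gene, and one common-variant gene.
make_top_gene_cohort <- function(n_cases = 71, n_controls = 1926) {
  cases <- sprintf("case%03d", seq_len(n_cases))
  controls <- sprintf("ctrl%04d", seq_len(n_controls))
  v <- rbind(
    make_variants("10", 101:105, "CH25H"),              # novel missense
    make_variants("10", 201:202, "SYNGENE", "synonymous"),
    make_variants("12", 301, "COMMONG", kg1000 = 0.02))
  calls <- rbind(
    make_calls(cases[1:3], v$key[1:3]),
    make_calls(controls[1:2], v$key[4:5]),
    make_calls(c(cases[4], controls[3]), v$key[6:7]),
    make_calls(cases[5], v$key[8]))
  fh_cohort(cases, controls, calls, v)
}

write_vcf_lines <- function(path, samples, records) {
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}

write_annotation_tsv <- function(path, variants) {
  write.table(variants[setdiff(names(variants), "key")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}
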