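make_catalogue <- function() {
  validate_catalogue(data.frame(
    gene = c("APOB", "LDLRAP1", "LDLRAP1", "LDLR", "APOB"),
    chrom = c("2", "1", "1", "19", "2"),
    pos = c(21229160L, 25870520L, 25871000L, 11216230L, 21230600L),
    ref = c("C", "T", "G", "C", "G"),
    alt = c("T", "TA", "A", "T", "A"),
    hgvs_c = c("c.10580G>A", "c.432_433insA", "c.500G>A", "c.1060C>T",
               "c.148G>A"),
    pathogenicity = c("known_fh", "known_fh", "known_fh", "known_fh",
                      "unknown_effect"),
    stringsAsFactors = FALSE))
}

tier1_cohort <- function(calls, extra_variants = NULL) {
  cat_df <- make_catalogue()
  v <- make_variants(cat_df$chrom, cat_df$pos, cat_df$gene,
                     ref = cat_df$ref, alt = cat_df$alt,
                     hgvs_c = cat_df$hgvs_c)
  if (!is.null(extra_variants)) v <- rbind(v, extra_variants)
  fh_cohort(sprintf("case%02d", 1:8), sprintf("ctrl%02d", 1:4),
            calls, v)
}

test_that("a known dominant mutation explains its carrier", {
  cat_df <- make_catalogue()
  co <- tier1_cohort(make_calls("case01", "2:21229160:C:T"))
  sc <- screen_tier1(co, cat_df)
  expect_identical(sc$explained, "case01")
  expect_true(all(sc$matches$explains))
  expect_identical(sc$matches$hgvs_c, "c.10580G>A")  # traceability
})

test_that("recessive-model genes need two hits to explain", {
  cat_df <- make_catalogue()
  # single het LDLRAP1 frameshift: reported, not explanatory
  one <- screen_tier1(tier1_cohort(make_calls("case02", "1:25870520:T:TA")),
                      cat_df)
  expect_identical(nrow(one$matches), 1L)
  expect_false(one$matches$explains)
  expect_length(one$explained, 0)
  # homozygous: explained
  hom <- screen_tier1(
    tier1_cohort(make_calls("case02", "1:25870520:T:TA", "hom")), cat_df)
  expect_identical(hom$explained, "case02")
  # two distinct het hits in the gene: explained (compound het model)
  two <- screen_tier1(
    tier1_cohort(make_calls(c("case02", "case02"),
                            c("1:25870520:T:TA", "1:25871000:G:A"))),
    cat_df)
  expect_identical(two$explained, "case02")
})

test_that("unknown-effect entries are reported but never explanatory", {
  sc <- screen_tier1(tier1_cohort(make_calls("case03", "2:21230600:G:A")),
                     make_catalogue())
  expect_identical(nrow(sc$matches), 1L)
  expect_false(sc$matches$explains)
  expect_length(sc$explained, 0)
})

test_that("screening is order-independent, matches by HGVS fallback, and validates config", {
  cat_df <- make_catalogue()
  calls <- make_calls(c("case01", "case04", "case02"),
                      c("2:21229160:C:T", "19:11216230:C:T",
                        "1:25870520:T:TA"))
  co <- tier1_cohort(calls)
  co_rev <- tier1_cohort(calls[3:1, ])
  expect_identical(screen_tier1(co, cat_df)$matches,
                   screen_tier1(co_rev, cat_df)$matches)
  # empty catalogue: zero matches
  empty <- screen_tier1(co, cat_df[0, ])
  expect_identical(nrow(empty$matches), 0L)
  # catalogue entry outside Tier-1 genes is a fatal config error
  bad <- make_catalogue(); bad$gene[1] <- "CH25H"
  expect_error(validate_catalogue(bad), "non-Tier-1")
  # HGVS fallback: same mutation annotated at a drifted coordinate
  drifted <- make_variants("19", 99999, "LDLR", hgvs_c = "c.1060C>T",
                           ref = "C", alt = "T")
  co2 <- tier1_cohort(make_calls("case05", drifted$key),
                      extra_variants = drifted)
  sc2 <- screen_tier1(co2, cat_df)
  expect_identical(sc2$explained, "case05")
})

test_that("shipped example configuration files load through the readers", {
  w <- read_snp_weights(system.file("extdata",
                                    "score_weights_synthetic.tsv",
                                    package = "fhburden"))
  expect_identical(nrow(w), 12L)
  expect_true(all(w$provenance == "synthetic"))
  cat_df <- read_mutation_catalogue(
    system.file("extdata", "tier1_catalogue_synthetic.tsv",
                package = "fhburden"))
  expect_true("2:21229160:C:T" %in% cat_df$key)
  genes <- read_gene_list(system.file("extdata",
                                      "tier2_genes_example.txt",
                                      package = "fhburden"))
  expect_true(all(c("INSIG2", "LDLR") %in% genes))
  expect_false(any(grepl("^#", genes)))
})

test_that("triage gives Tier-1 precedence over a high score", {
  cat_df <- make_catalogue()
  co <- tier1_cohort(make_calls("case01", "2:21229160:C:T"))
  sc <- screen_tier1(co, cat_df)
  scores <- data.frame(sample_id = c("case01", "case02", "case03"),
                       total = c(1.5, 1.3, 0.8),
                       complete = TRUE, stringsAsFactors = FALSE)
  scores <- classify_polygenic(scores)
  tri <- triage_samples(co$cases, sc, scores)
  expect_identical(tri$status[tri$sample_id == "case01"],
                   "tier1_mutation")
  expect_identical(tri$status[tri$sample_id == "case02"], "polygenic")
  expect_identical(tri$status[tri$sample_id == "case03"], "unexplained")
  expect_identical(tri$status[tri$sample_id == "case04"], "unexplained")
})
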