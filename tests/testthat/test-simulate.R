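test_that("the same seed reproduces the simulation exactly", {
  cfg <- sim_config(seed = 33, n_cases = 30, n_controls = 100,
                    genes = default_gene_panel(60), n_tier1 = 3,
                    tier1_high_overlap = 1, polygenic_fraction = 0.2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$calls, b$cohort$calls)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    a$cohort$calls, simulate_cohort(sim_config(
      seed = 34, n_cases = 30, n_controls = 100,
      genes = default_gene_panel(60), n_tier1 = 3,
      tier1_high_overlap = 1, polygenic_fraction = 0.2))$cohort$calls))
})

test_that("zero rates give an empty call set; invalid configs are fatal", {
  genes <- default_gene_panel(10)
  genes$rate <- 0
  sim <- simulate_cohort(sim_config(seed = 1, n_cases = 5,
                                    n_controls = 5, genes = genes,
                                    n_tier1 = 0, tier1_high_overlap = 0,
                                    score_model = NULL,
                                    common_missense_rate = 0,
                                    novel_synonymous_rate = 0))
  expect_identical(nrow(sim$cohort$calls), 0L)
  expect_error(sim_config(), "seed")
  g2 <- default_gene_panel(5)
  expect_error(sim_config(seed = 1, genes = g2,
                          enrichment = c(G0001 = 1e5)), "exceeds 1")
  expect_error(sim_config(seed = 1, genes = g2,
                          enrichment = c(NOPE = 2)), "not in the gene")
})

test_that("spiked mutations normalize to catalogue keys and are fully recovered", {
  sim <- simulate_cohort(sim_config(seed = 12, n_cases = 50,
                                    n_controls = 80,
                                    genes = default_gene_panel(30),
                                    n_tier1 = 10, tier1_high_overlap = 0,
                                    score_model = NULL))
  expect_true(all(sim$truth$tier1_samples$key %in%
                    sim$config$catalogue$key))
  rec <- recover_parameters(sim)
  expect_equal(rec$tier1_recall, 1)
  expect_identical(rec$tier1_found, 10L)
  # the spike survives a write/read round trip through the VCF path
  tmp <- withr::local_tempdir()
  paths <- write_sim_inputs(sim, tmp)
  back <- read_cohort(paths["cases"], paths["controls"],
                      paths["annotation"])
  sc <- screen_tier1(back, sim$config$catalogue)
  expect_setequal(sc$explained,
                  unique(sim$truth$tier1_samples$sample_id))
})

test_that("planted case-enrichment surfaces with the expected counts", {
  genes <- default_gene_panel(100)
  g_idx <- 60
  rate <- genes$rate[g_idx]
  mult <- (3 / 71) / rate   # aim for ~3 case events in 71 cases
  reps <- lapply(1:30, function(r) {
    cfg <- sim_config(seed = 1000 + r, n_cases = 71, n_controls = 1926,
                      genes = genes,
                      enrichment = setNames(mult, genes$gene[g_idx]),
                      n_tier1 = 0, tier1_high_overlap = 0,
                      polygenic_fraction = 0, score_model = NULL,
                      common_missense_rate = 0,
                      novel_synonymous_rate = 0)
    sim <- simulate_cohort(cfg)
    counts <- collect_gene_counts(sim$cohort, "novel")
    k <- counts[counts$gene == genes$gene[g_idx], ]
    if (nrow(k)) c(k$k_case, k$k_control) else c(0L, 0L)
  })
  m <- colMeans(do.call(rbind, reps))
  expect_equal(m[1], 3, tolerance = 0.35)               # ~3 case events
  expect_equal(m[2], 1926 * rate, tolerance = 0.5)      # background
})

test_that("the generated control score distribution hits its targets as n grows", {
  cfg <- sim_config(seed = 77, n_cases = 2, n_controls = 8000,
                    genes = default_gene_panel(5), n_tier1 = 0,
                    tier1_high_overlap = 0, polygenic_fraction = 0,
                    score_missing_fraction = 0)
  sim <- simulate_cohort(cfg)
  scores <- gene_score(sim$genotypes, cfg$score_model$snps, sim$apoe)
  ctrl <- scores$total[match(sim$cohort$controls, scores$sample_id)]
  expect_equal(mean(ctrl), 0.90, tolerance = 0.02)
  expect_equal(quantile(ctrl, 0.9, names = FALSE), 1.16,
               tolerance = 0.03)
})

test_that("planted high-score fractions and missingness are exact by construction", {
  cfg <- sim_config(seed = 8)   # study defaults: 125/1926, 25/2/0.29
  sim <- simulate_cohort(cfg)
  rec <- recover_parameters(sim)
  expect_equal(rec$planted_fraction, 0.29)
  expect_equal(rec$recovered_fraction, 0.29)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$specificity, 1)
  # 16 of 125 cases unscorable, as configured
  scores <- rec$scores
  case_cls <- scores$classification[match(sim$cohort$cases,
                                          scores$sample_id)]
  expect_identical(sum(case_cls == "unscored"), 16L)
})
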