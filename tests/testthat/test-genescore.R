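toy_weights <- function(w = c(0.1, 0.2, 0.3)) {
  data.frame(snp_id = paste0("rs", seq_along(w)),
             effect_allele = "A", other_allele = "G", weight = w,
             stringsAsFactors = FALSE)
}

toy_genotypes <- function(sample_id, dosages, weights = toy_weights()) {
  do.call(rbind, lapply(seq_along(sample_id), function(i) {
    d <- dosages[[i]]
    data.frame(sample_id = sample_id[i], snp_id = weights$snp_id,
               allele1 = ifelse(d >= 1, "A", "G"),
               allele2 = ifelse(d == 2, "A", "G"),
               stringsAsFactors = FALSE)
  }))
}

test_that("APOE diplotype scoring matches the fixed table, unordered", {
  expect_equal(apoe_score(c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4",
                            "e4e4")),
               c(-0.9, -0.4, -0.2, 0, 0.1, 0.2))
  expect_equal(apoe_score("e4e2"), apoe_score("e2e4"))
  expect_equal(apoe_score("E3/E4"), 0.1)
  expect_true(is.na(apoe_score(NA)))
  expect_error(apoe_score("e1e3"), "invalid APOE")
})

test_that("APOE diplotype derives from rs429358/rs7412 with e2e4 double-het convention", {
  expect_identical(apoe_from_snps("T/T", "C/C"), "e3e3")
  expect_identical(apoe_from_snps("C/C", "C/C"), "e4e4")
  expect_identical(apoe_from_snps("T/T", "T/T"), "e2e2")
  expect_identical(apoe_from_snps("C/T", "C/C"), "e3e4")
  expect_identical(apoe_from_snps("T/T", "C/T"), "e2e3")
  # ambiguous double heterozygote: only phase without an e1 allele
  expect_identical(apoe_from_snps("C/T", "C/T"), "e2e4")
  # missing genotype or an e1-implying combination is unavailable
  expect_true(is.na(apoe_from_snps(NA, "C/C")))
  expect_true(is.na(apoe_from_snps("C/C", "T/T")))
  expect_error(apoe_from_snps("A/T", "C/C"), "rs429358")
})

test_that("gene score sums weight times effect-allele dosage plus APOE", {
  w <- toy_weights()
  apoe <- data.frame(sample_id = c("s0", "s2", "s3"),
                     apoe = c("e3e3", "e2e2", "e3e4"))
  g <- toy_genotypes(c("s0", "s2", "s3"),
                     list(c(0, 0, 0), c(0, 0, 0), c(2, 1, 0)))
  res <- gene_score(g, w, apoe)
  expect_equal(res$total[res$sample_id == "s0"], 0)
  expect_equal(res$total[res$sample_id == "s2"], -0.9)
  expect_equal(res$total[res$sample_id == "s3"], 0.1 * 2 + 0.2 * 1 + 0.1)
  expect_true(all(res$complete))
})

test_that("any missing SNP or APOE leaves a sample unscored, never imputed", {
  w <- toy_weights()
  g <- toy_genotypes(c("s1", "s2"), list(c(1, 1, 1), c(1, 1, 1)))
  g <- g[!(g$sample_id == "s2" & g$snp_id == "rs2"), ]  # drop one SNP
  apoe <- data.frame(sample_id = c("s1", "s2"), apoe = "e3e3")
  res <- classify_polygenic(gene_score(g, w, apoe), cutoff = 0.3)
  expect_true(res$complete[res$sample_id == "s1"])
  expect_false(res$complete[res$sample_id == "s2"])
  expect_true(is.na(res$total[res$sample_id == "s2"]))
  expect_identical(res$classification[res$sample_id == "s2"], "unscored")
  # missing APOE likewise
  res2 <- gene_score(toy_genotypes("s3", list(c(1, 1, 1))), w,
                     data.frame(sample_id = "s3", apoe = NA))
  expect_false(res2$complete)
  # an allele outside the effect/other pair is a data error naming the SNP
  bad <- toy_genotypes("s4", list(c(1, 1, 1)))
  bad$allele1[bad$snp_id == "rs3"] <- "T"
  expect_error(gene_score(bad, w,
                          data.frame(sample_id = "s4", apoe = "e3e3")),
               "rs3")
})

test_that("score is additive and invariant to SNP order", {
  set.seed(5)
  w <- toy_weights(runif(6, 0.01, 0.2))
  d <- sample(0:2, 6, replace = TRUE)
  g <- toy_genotypes("s1", list(d), w)
  apoe <- data.frame(sample_id = "s1", apoe = "e3e4")
  base <- gene_score(g, w, apoe)
  perm <- sample(nrow(g))
  expect_equal(gene_score(g[perm, ], w, apoe)$total, base$total)
  expect_equal(base$snp_component, sum(w$weight * d))
  expect_equal(base$total, base$snp_component + base$apoe_component)
})

test_that("polygenic classification is strict at the cutoff and monotone in it", {
  sc <- data.frame(sample_id = c("a", "b", "c"),
                   total = c(1.17, 1.16, 0.90), complete = TRUE)
  cls <- classify_polygenic(sc, 1.16)$classification
  expect_identical(cls, c("polygenic", "not_polygenic", "not_polygenic"))
  # lowering the cutoff (1.08, the 9th-decile alternative) adds samples
  cls108 <- classify_polygenic(sc, 1.08)$classification
  expect_identical(cls108, c("polygenic", "polygenic", "not_polygenic"))
  # raising the cutoff never adds polygenic samples
  for (cut in c(0.5, 1.0, 1.16, 1.4)) {
    lower <- sum(classify_polygenic(sc, cut)$classification == "polygenic")
    higher <- sum(classify_polygenic(sc, cut + 0.1)$classification ==
                    "polygenic")
    expect_lte(higher, lower)
  }
})

test_that("group comparisons use Welch t and one-way ANOVA", {
  set.seed(9)
  # identical groups: t ~ 0, p ~ 1
  x <- rnorm(50, 1, 0.2)
  same <- compare_groups(list(a = x, b = x))
  expect_lt(abs(same$pairwise$t), 1e-10)
  expect_gt(same$pairwise$p, 0.999)
  # separated means, unequal n: strongly significant (Welch handles
  # the variance imbalance)
  g <- list(control = rnorm(3020, 0.90, 0.23),
            mutation_negative = rnorm(83, 1.08, 0.23),
            mutation_positive = rnorm(21, 0.96, 0.23))
  cmp <- compare_groups(g)
  p_cn <- cmp$pairwise$p[cmp$pairwise$group1 == "control" &
                           cmp$pairwise$group2 == "mutation_negative"]
  expect_lt(p_cn, 0.01)
  expect_lt(cmp$anova_p, 0.01)
  # cross-check our Welch p against stats::t.test directly
  expect_equal(p_cn, t.test(g$control, g$mutation_negative)$p.value)
  # groups with fewer than two values are not computable
  tiny <- compare_groups(list(a = rnorm(10), b = 1))
  expect_true(is.na(tiny$pairwise$p))
  expect_error(compare_groups(list(a = numeric(), b = numeric())),
               "non-empty")
})

test_that("ANOVA p-values are roughly uniform under the null", {
  set.seed(21)
  ps <- replicate(200, {
    g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    compare_groups(g)$anova_p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
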