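test_that("genotype simulation is deterministic and respects HWE", {
  cfg <- simulation_config(n_individuals = 200, n_variants = 100, seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)
  expect_true(all(g1$dosages %in% c(0, 1, 2) | is.na(g1$dosages)))

  # HWE at maf 0.5 with a single variant: counts near n/4, n/2, n/4
  cfg2 <- simulation_config(n_individuals = 10000, n_variants = 1,
                            maf_range = c(0.5, 0.5), ld_block_size = 1,
                            missing_rate = 0, seed = 9)
  g <- simulate_genotypes(cfg2)
  counts <- table(factor(g$dosages, levels = 0:2))
  expect_gt(hwe_test(counts[[3]], counts[[2]], counts[[1]]), 1e-4)
  expect_equal(unname(counts[[2]]) / 10000, 0.5, tolerance = 0.05)
})

test_that("LD structure follows the block configuration", {
  # no LD: mean absolute off-diagonal correlation is small
  cfg0 <- simulation_config(n_individuals = 2000, n_variants = 40,
                            ld_rho = 0, missing_rate = 0, seed = 3)
  g0 <- simulate_genotypes(cfg0)
  c0 <- cor(g0$dosages)
  expect_lt(mean(abs(c0[upper.tri(c0)])), 0.05)

  # strong LD: adjacent within-block correlation clearly above the
  # between-block level
  cfg1 <- simulation_config(n_individuals = 2000, n_variants = 40,
                            ld_rho = 0.8, ld_block_size = 10,
                            missing_rate = 0, seed = 3)
  g1 <- simulate_genotypes(cfg1)
  c1 <- cor(g1$dosages)
  within <- mean(abs(c1[cbind(1:9, 2:10)]))
  lay <- g1$variants
  between <- abs(c1[10, 11])  # last SNP of block 1 vs first of block 2
  expect_gt(within, 0.4)
  expect_lt(between, 0.1)
})

test_that("summary statistics carry calibrated null p-values and a strong causal tier", {
  # pure null: p-values uniform
  cfg <- simulation_config(n_individuals = 50, n_variants = 5000,
                           n_causal = 10, effect_sd = 0, seed = 21)
  g <- simulate_genotypes(cfg)
  ss <- simulate_summary_stats(cfg, g)
  expect_lt(abs(mean(ss$pvalue < 0.05) - 0.05), 0.015)

  # one causal variant with an enormous discovery sample reaches 5e-8
  cfg2 <- simulation_config(n_individuals = 50, n_variants = 10,
                            n_causal = 1, effect_sd = 0.3,
                            n_discovery = 1e8, seed = 22)
  g2 <- simulate_genotypes(cfg2)
  ss2 <- simulate_summary_stats(cfg2, g2)
  causal <- attr(ss2, "causal_idx")
  expect_lt(ss2$pvalue[causal], 5e-8)

  # determinism
  ss3 <- simulate_summary_stats(cfg2, g2)
  expect_identical(ss2$beta, ss3$beta)
})

test_that("marker profiles respect prevalence, liability coupling and missingness", {
  cfg <- simulation_config(n_individuals = 5000, n_variants = 10,
                           liability_loading = 0, seed = 31)
  scores <- rnorm(5000)
  prof <- simulate_markers(cfg, scores, sprintf("i%04d", 1:5000))
  expect_setequal(
    setdiff(lr_marker_names(load_lr_table()), names(prof)), character(0))
  # zero loading: deficit independent of the score
  deficit <- as.numeric(prof$global_cognitive_deficit == "present")
  expect_lt(abs(cor(scores, deficit)), 0.05)
  # erectile dysfunction always missing for females
  expect_true(all(prof$erectile_dysfunction[prof$sex == "female"] == "missing"))

  # positive loading: logistic slope of deficit on the score is recovered
  cfg2 <- simulation_config(n_individuals = 5000, n_variants = 10,
                            liability_loading = 0.5, seed = 32)
  prof2 <- simulate_markers(cfg2, scores, sprintf("i%04d", 1:5000))
  d2 <- data.frame(y = as.numeric(prof2$global_cognitive_deficit == "present"),
                   s = scores)
  d2 <- d2[prof2$global_cognitive_deficit != "missing", ]
  fit <- glm(y ~ s, family = binomial(), data = d2)
  expect_gt(coef(fit)[["s"]], 0)  # higher genetic liability, more deficit
  expect_gt(coef(fit)[["s"]] / sqrt(diag(vcov(fit)))[["s"]], 3)

  # marker missing_rate = 1 forces every maskable marker to missing
  cfg3 <- simulation_config(n_individuals = 50, n_variants = 10,
                            missing_rate = 1, seed = 33)
  prof3 <- simulate_markers(cfg3, rnorm(50), sprintf("i%02d", 1:50))
  expect_true(all(prof3$constipation == "missing"))
  expect_true(all(prof3$dm2 == "missing"))
})

test_that("marker generation fails on id/score length mismatch", {
  cfg <- simulation_config(n_individuals = 10, n_variants = 10)
  expect_error(simulate_markers(cfg, rnorm(10), sprintf("i%d", 1:9)),
               "mismatch")
})

test_that("cohort simulation is reproducible end to end", {
  cfg <- simulation_config(n_individuals = 60, n_variants = 80, seed = 12)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$dosages, c2$genotypes$dosages)
  expect_identical(c1$sumstats, c2$sumstats)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$true_scores, c2$true_scores)
  expect_true(all(c1$profiles$individual_id == c1$genotypes$individual_ids))
})

test_that("failure injection updates only its targets and logs the truth", {
  cfg <- simulation_config(n_individuals = 80, n_variants = 120, seed = 8)
  co <- simulate_cohort(cfg)
  expect_identical(inject_qc_failures(co, list()), co)
  expect_error(inject_qc_failures(co, list(not_a_kind = 1)), "unknown")

  co2 <- inject_qc_failures(co, list(duplicate_sample = 1,
                                     hwe_violation = 1))
  pair <- co2$truth_log$duplicate_sample[[1]]
  kin <- estimate_kinship(co2$genotypes)
  expect_gt(kin[pair[1], pair[2]], 0.9)

  hw <- co2$truth_log$hwe_violation
  col <- co2$genotypes$dosages[, hw]
  expect_true(all(col == 1))
  expect_lt(hwe_test(sum(col == 2), sum(col == 1), sum(col == 0)), 5e-8)

  # untouched entries bit-identical
  clean_vars <- setdiff(co$genotypes$variants$variant_id, hw)
  expect_identical(co2$genotypes$dosages[co$genotypes$individual_ids,
                                         clean_vars],
                   co$genotypes$dosages[, clean_vars])
})
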