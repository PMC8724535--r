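test_that("sample QC excludes by missingness then heterozygosity", {
  set.seed(41)
  n <- 500; m <- 400
  d <- sapply(runif(m, 0.2, 0.5), function(p) rbinom(n, 2, p))
  # sample 1: 6% missing calls; sample 2: all heterozygous
  d[1, sample.int(m, 24)] <- NA
  d[2, ] <- 1
  gm <- make_gm(d)
  sq <- sample_qc(gm)
  expect_equal(unname(sq$excluded[gm$individual_ids[1]]), "missingness")
  expect_equal(unname(sq$excluded[gm$individual_ids[2]]), "heterozygosity")
  # an ordinary fully-observed sample is kept
  expect_true(gm$individual_ids[3] %in% sq$kept)
  expect_match(sq$skipped_checks, "sex_check")
})

test_that("sample QC does not depend on input row order", {
  set.seed(42)
  d <- sapply(runif(200, 0.2, 0.5), function(p) rbinom(100, 2, p))
  d[5, sample.int(200, 14)] <- NA
  gm <- make_gm(d)
  perm <- sample(nrow(d))
  gmp <- subset_genotypes(gm, individuals = gm$individual_ids[perm])
  s1 <- sample_qc(gm)
  s2 <- sample_qc(gmp)
  expect_setequal(names(s1$excluded), names(s2$excluded))
  expect_setequal(s1$kept, s2$kept)
})

test_that("hwe_test matches the closed-form oracle and its landmarks", {
  expect_equal(hwe_test(25, 50, 25), 1)
  expect_lt(hwe_test(0, 1000, 0), 5e-8)
  expect_equal(hwe_test(300, 500, 200), oracle_hwe(300, 500, 200),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:100) {
    cnt <- rmultinom(1, sample(50:2000, 1), prob = runif(3, 0.05, 1))
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  expect_error(hwe_test(0, 0, 0), "positive")
})

test_that("kinship estimator recovers identity, duplicates and independence", {
  set.seed(43)
  n <- 40; m <- 5000
  maf <- runif(m, 0.1, 0.5)
  d <- sapply(maf, function(p) rbinom(n, 2, p))
  d <- rbind(d, d[1, ])  # duplicate of sample 1
  gm <- make_gm(d, pos = seq_len(m) * 1e4)
  kin <- estimate_kinship(gm)
  expect_equal(unname(diag(kin)), rep(1, n + 1))
  expect_gt(kin[1, n + 1], 0.9)
  expect_lt(kin[2, 3], 0.05)  # independent pair
  expect_error(estimate_kinship(subset_genotypes(gm, individuals = "s001")),
               "at least 2")
})

test_that("kinship filter prunes greedily with deterministic ties", {
  ids <- c("a", "b", "c")
  k <- diag(3); dimnames(k) <- list(ids, ids)
  k["a", "b"] <- k["b", "a"] <- 0.6
  expect_setequal(kinship_filter(k, 0.125), "b")  # tie -> larger id removed
  miss <- c(a = 0.04, b = 0.01, c = 0)
  expect_setequal(kinship_filter(k, 0.125, miss), "a")  # higher missingness
  expect_length(kinship_filter(diag(3), 0.125), 0)

  # triangle of mutual relatives: <= 2 removed, remainder below cutoff
  k3 <- matrix(0.5, 3, 3); diag(k3) <- 1; dimnames(k3) <- list(ids, ids)
  rem <- kinship_filter(k3, 0.125)
  expect_lte(length(rem), 2)
  keep <- setdiff(ids, rem)
  if (length(keep) > 1)
    expect_true(all(k3[keep, keep][upper.tri(diag(length(keep)))] <= 0.125))
})

test_that("PCA separates populations, yields orthonormal axes, flags shifts", {
  set.seed(44)
  n <- 200; m <- 400
  p1 <- runif(m, 0.1, 0.5)
  p2 <- pmin(0.95, p1 + 0.3)  # mean-shifted subpopulation
  d <- rbind(sapply(p1, function(p) rbinom(n / 2, 2, p)),
             sapply(p2, function(p) rbinom(n / 2, 2, p)))
  gm <- make_gm(d)
  pc <- pca_project(gm, k = 2)
  groups <- rep(c(0, 1), each = n / 2)
  expect_gt(abs(cor(pc$pcs[, "MDSC1"], groups)), 0.9)
  expect_equal(crossprod(pc$pcs), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)

  # homogeneous cohort: no 6-SD outliers
  d0 <- sapply(p1, function(p) rbinom(n, 2, p))
  pc0 <- pca_project(make_gm(d0), k = 2)
  expect_length(pc0$outliers, 0)
  expect_error(pca_project(make_gm(d0[1:3, 1:2]), k = 5), "rank")
})

test_that("variant QC applies each exclusion rule with its own reason", {
  set.seed(45)
  n <- 400
  mafs <- c(0.45, 0.10, 0.30, 0.30, 0.25, 0.25)
  d <- sapply(mafs, function(p) rbinom(n, 2, p))
  d[, 4] <- d[, 3]             # duplicate of variant 3, worse missingness
  d[sample.int(n, 12), 4] <- NA
  d[, 5] <- 1                  # all-heterozygous: HWE violation
  gm <- genotype_matrix(
    d,
    data.frame(variant_id = paste0("v", 1:6),
               chrom = 1, pos = c(1e4, 2e4, 3e4, 3e4, 4e4, 5e4),
               ref = c("A", "A", "C", "C", "A", "T"),
               alt = c("T", "T", "T", "T", "G", "C"),
               stringsAsFactors = FALSE),
    sprintf("s%03d", 1:n))
  vq <- variant_qc(gm)
  expect_equal(unname(vq$excluded[["v1"]]), "ambiguous")  # A/T, MAF ~0.45
  expect_false("v2" %in% names(vq$excluded))              # A/T but MAF 0.10
  expect_equal(unname(vq$excluded[["v4"]]), "duplicate")  # higher missingness
  expect_true("v3" %in% vq$kept)                          # lower missingness kept
  expect_equal(unname(vq$excluded[["v5"]]), "hwe")
})

test_that("differential missingness across batches is detected", {
  set.seed(46)
  n <- 600
  d <- sapply(runif(5, 0.2, 0.5), function(p) rbinom(n, 2, p))
  batch <- rep(c("A", "B"), each = n / 2)
  d[batch == "A", 1][sample.int(n / 2, 90)] <- NA  # 30% missing in batch A only
  gm <- make_gm(d)
  vq <- variant_qc(gm, batch_labels = batch)
  expect_true(unname(vq$excluded[["snp001"]]) %in%
                c("missingness", "differential_missingness"))
  vq2 <- variant_qc(gm, batch_labels = batch,
                    thresholds = qc_thresholds(variant_missingness_max = 0.5))
  expect_equal(unname(vq2$excluded[["snp001"]]), "differential_missingness")
  expect_error(variant_qc(gm, batch_labels = batch[1:10]), "length")
})

test_that("full QC is idempotent", {
  # at the scale the QC stage is designed for: with very small marker
  # panels the kinship noise floor dominates and no pairwise rule is stable
  cfg <- simulation_config(n_individuals = 500, n_variants = 2000, seed = 47)
  co <- simulate_cohort(cfg)
  q1 <- run_genotype_qc(co$genotypes)
  q2 <- run_genotype_qc(q1$kept_matrix)
  expect_setequal(q2$kept_matrix$individual_ids, q1$kept_matrix$individual_ids)
  expect_setequal(q2$kept_matrix$variants$variant_id,
                  q1$kept_matrix$variants$variant_id)
})
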