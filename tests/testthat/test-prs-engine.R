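test_that("allele harmonization resolves direct, swapped and flipped matches", {
  variants <- data.frame(variant_id = c("v1", "v2", "v3", "v4", "v5"),
                         chrom = 1, pos = c(100, 200, 300, 400, 500),
                         ref = "G", alt = "A", stringsAsFactors = FALSE)
  ss <- data.frame(chrom = 1, pos = c(100, 200, 300, 400),
                   effect_allele = c("A", "G", "T", "C"),
                   other_allele = c("G", "A", "C", "T"),
                   beta = 0.3, pvalue = 1e-5, stringsAsFactors = FALSE)
  h <- harmonize_sumstats(variants, ss)
  expect_equal(h$beta[h$variant_id == "v1"], 0.3)    # direct
  expect_equal(h$beta[h$variant_id == "v2"], -0.3)   # swapped
  expect_equal(h$beta[h$variant_id == "v3"], 0.3)    # strand flip
  expect_equal(h$beta[h$variant_id == "v4"], -0.3)   # flip + swap
  expect_false("v5" %in% h$variant_id)               # unmatched position
  counts <- attr(h, "match_counts")
  expect_equal(unname(counts["flipped"]), 2L)

  # ambiguous variant matchable only by flip is dropped
  va <- data.frame(variant_id = "amb", chrom = 1, pos = 10,
                   ref = "A", alt = "T", stringsAsFactors = FALSE)
  sa <- data.frame(chrom = 1, pos = 10, effect_allele = "C",
                   other_allele = "G", beta = 1, pvalue = 0.5)
  ha <- harmonize_sumstats(va, sa)
  expect_equal(nrow(ha), 0)
  expect_equal(unname(attr(ha, "match_counts")["ambiguous_dropped"]), 1L)

  # duplicate positions are a QC contract violation
  expect_error(harmonize_sumstats(rbind(variants, variants[1, ]), ss),
               "duplicate")
})

test_that("target filters are strict and default imputation quality passes", {
  v <- data.frame(variant_id = c("a", "b", "c", "d"),
                  chrom = 1, pos = 1:4, ref = "A", alt = "G",
                  maf = c(0.05, 0.30, 0.30, 0.30),
                  call_rate = c(0.99, 0.99, 0.95, 0.99),
                  info_score = c(0.9, 0.9, 0.9, NA))
  kept <- filter_target_variants(v)
  expect_false("a" %in% kept$variant_id)  # maf exactly on the bound
  expect_false("c" %in% kept$variant_id)  # call rate exactly on the bound
  expect_true(all(c("b", "d") %in% kept$variant_id))  # NA info -> 1.0
})

test_that("greedy clumping keeps the best SNP and respects window and MHC", {
  set.seed(51)
  n <- 300
  base <- rbinom(n, 1, 0.4) + rbinom(n, 1, 0.4)
  noisy <- function(x) { i <- sample.int(n, 15); x[i] <- 2 - x[i]; x }
  d <- cbind(base, noisy(base), base, sapply(1:2, function(i) rbinom(n, 2, 0.3)))
  colnames(d) <- NULL
  gm <- make_gm(d, chrom = c(1, 1, 1, 6, 2),
                pos = c(1e5, 1.1e5, 4.1e5, 28e6, 1e5))
  h <- data.frame(variant_id = gm$variants$variant_id,
                  chrom = gm$variants$chrom, pos = gm$variants$pos,
                  beta = 1, pvalue = c(1e-10, 1e-4, 1e-6, 1e-20, 0.01))
  cl <- clump_variants(h, gm)
  # snp002 is within 10 kb and r2 ~ 0.8 with snp001 -> removed;
  # snp003 is identical but 310 kb away -> retained;
  # snp004 sits in the MHC -> excluded before clumping despite best p
  expect_setequal(cl$variant_id, c("snp001", "snp003", "snp005"))
  expect_equal(cl$variant_id[1], "snp001")  # selection order by p

  expect_equal(nrow(clump_variants(h[0, ], gm)), 0)
  single <- clump_variants(h[5, , drop = FALSE], gm)
  expect_equal(single$variant_id, "snp005")
})

test_that("thresholding is strict and nested", {
  cl <- data.frame(variant_id = paste0("v", 1:6), chrom = 1,
                   pos = 1:6, beta = 1,
                   pvalue = c(1e-9, 1e-5, 0.03, 0.07, 0.2, 0.45))
  expect_equal(nrow(select_by_threshold(cl, 1.0)), 6)
  expect_equal(select_by_threshold(cl, 5e-8)$variant_id, "v1")
  s1 <- select_by_threshold(cl, 1e-4)
  s2 <- select_by_threshold(cl, 0.05)
  expect_true(all(s1$variant_id %in% s2$variant_id))
  # strict comparison: a p-value exactly at the cutoff is excluded
  expect_false("v3" %in% select_by_threshold(cl, 0.03)$variant_id)
})

test_that("scoring matches hand-computed weighted sums", {
  d <- matrix(c(2, 1, 0,
                0, 2, NA), nrow = 3)
  gm <- make_gm(d)
  snps <- data.frame(variant_id = c("snp001", "snp002"), beta = c(0.5, 1))
  s <- prs_score(gm, snps)
  # sample 3: missing dosage at snp002 imputed with mean dosage 2*0.5 = 1
  expect_equal(unname(s), c(2 * 0.5 + 0, 1 * 0.5 + 2, 0 * 0.5 + 1 * 1),
               tolerance = 1e-12)
  # zero weights give zero scores; doubled betas double scores exactly
  expect_equal(unname(prs_score(gm, transform(snps, beta = 0))), c(0, 0, 0))
  expect_equal(prs_score(gm, transform(snps, beta = beta * 2)), s * 2,
               tolerance = 1e-12)
  expect_error(prs_score(gm, data.frame(variant_id = "nope", beta = 1)),
               "absent")
})

test_that("quartile labels follow rank arithmetic with ties to the lower quartile", {
  q <- quartilize(1:8)
  expect_equal(as.character(q), paste0("Q", rep(1:4, each = 2)))
  expect_warning(qq <- quartilize(rep(1, 8)), "degenerate")
  expect_true(all(qq == "Q1"))
  set.seed(52)
  x <- rnorm(403)
  tab <- table(quartilize(x))
  expect_lte(max(tab) - min(tab), 1)
  expect_error(quartilize(1:3), "at least 4")
})

test_that("clumping agrees with a brute-force oracle on random fixtures", {
  set.seed(53)
  for (rep in 1:20) {
    m <- sample(5:30, 1)
    n <- 80
    d <- sapply(runif(m, 0.1, 0.5), function(p) rbinom(n, 2, p))
    # induce some LD by copying columns with noise
    for (j in seq_len(m)) if (runif(1) < 0.3 && j > 1) {
      d[, j] <- d[, j - 1]
      flip <- sample.int(n, 8)
      d[flip, j] <- sample(0:2, 8, TRUE)
    }
    chrom <- sample(c(1, 2, 6), m, TRUE)
    pos <- ifelse(chrom == 6, sample(26e6:34e6, m), sample(1e5:2e6, m))
    gm <- make_gm(d, chrom = chrom, pos = pos)
    h <- data.frame(variant_id = gm$variants$variant_id, chrom = chrom,
                    pos = pos, beta = 1, pvalue = runif(m))
    got <- clump_variants(h, gm)$variant_id
    want <- oracle_clump(h, imputed_dosages(gm))
    expect_identical(got, want)
  }
})

test_that("profiles across thresholds are nested and quartiled", {
  cfg <- simulation_config(n_individuals = 150, n_variants = 300, seed = 54)
  co <- simulate_cohort(cfg)
  prs <- build_prs_profiles(co$genotypes, co$sumstats)
  ns <- tapply(prs$n_snps, prs$threshold, unique)
  expect_true(all(diff(ns[order(as.numeric(names(ns)))]) >= 0))
  expect_true(all(table(prs$quartile[prs$threshold == 0.5]) >= 1))
  # MHC exclusion holds in the clumped set
  cl <- attr(prs, "clumped")
  expect_false(any(cl$chrom == 6 & cl$pos >= 27e6 & cl$pos <= 33e6))
})
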