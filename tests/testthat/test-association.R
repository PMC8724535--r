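test_that("linear fits are exact on noiseless data and match the OLS oracle", {
  d <- data.frame(x = 1:20, y = 2 * (1:20))
  r <- suppressWarnings(fit_linear(d, "y", "x"))  # "essentially perfect fit"
  expect_equal(r$estimate, 2, tolerance = 1e-10)
  expect_lt(r$ci_high - r$ci_low, 1e-8)

  set.seed(71)
  for (i in 1:20) {
    n <- 50
    d <- data.frame(x = rnorm(n), c1 = rnorm(n), c2 = rnorm(n))
    d$y <- 0.5 * d$x - 0.2 * d$c1 + rnorm(n)
    r <- fit_linear(d, "y", "x", c("c1", "c2"))
    want <- oracle_ols(cbind(1, d$x, d$c1, d$c2), d$y)
    expect_equal(r$estimate, want[2], tolerance = 1e-8)
  }
})

test_that("log-transformed outcomes drop non-positive rows with a count", {
  d <- data.frame(x = rnorm(50), y = exp(rnorm(50)))
  d$y[1:3] <- c(0, -1, 0)
  r <- fit_linear(d, "y", "x", transform = "natural_log")
  expect_equal(r$n_used, 47)
  expect_equal(attr(r, "n_dropped_nonpositive"), 3L)
  d$z <- d$x
  expect_error(fit_linear(d, "y", "x", "z"), "collinear")
})

test_that("logistic fits match a hand-rolled Newton oracle", {
  set.seed(72)
  n <- 400
  d <- data.frame(x = rnorm(n), c1 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-1 + 0.8 * d$x + 0.3 * d$c1))
  r <- fit_logistic(d, "y", "x", "c1")
  o <- oracle_logistic(cbind(1, d$x, d$c1), d$y)
  expect_equal(log(r$estimate), o$coef[2], tolerance = 1e-6)
  expect_equal(log(r$ci_high) - log(r$estimate), 1.96 * o$se[2],
               tolerance = 1e-4)
  expect_true(r$converged)
})

test_that("logistic recovery and degenerate designs behave as specified", {
  set.seed(73)
  n <- 5000
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-1 + 0.5 * d$x))
  r <- fit_logistic(d, "y", "x")
  se <- (log(r$ci_high) - log(r$estimate)) / 1.96
  expect_lt(abs(log(r$estimate) - 0.5), 3 * se)

  d$k <- 1
  expect_error(fit_logistic(d, "y", "k"), "constant")
  d$one <- 1L
  expect_error(fit_logistic(d, "one", "x"), "single class")
  # complete separation is flagged, not reported as a sound estimate
  ds <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                   y = c(rep(0, 20), rep(1, 20)))
  rs <- fit_logistic(ds, "y", "x")
  expect_false(rs$converged)
  expect_true(is.na(rs$estimate))
})

test_that("exposure odds ratio is invariant to covariate centering", {
  set.seed(74)
  n <- 800
  d <- data.frame(x = rnorm(n), age = runif(n, 65, 90))
  d$y <- rbinom(n, 1, plogis(-1 + 0.4 * d$x + 0.02 * d$age))
  r1 <- fit_logistic(d, "y", "x", "age")
  d$age <- d$age - mean(d$age)
  r2 <- fit_logistic(d, "y", "x", "age")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
})

test_that("quartile contrasts keep all rows and agree with the binary coding", {
  set.seed(75)
  n <- 2000
  score <- rnorm(n)
  q <- quartilize(score)
  d <- data.frame(q = q, y = rbinom(n, 1, plogis(-1.5 + 0.4 * (q == "Q4"))))
  res <- quartile_contrast(d, "y", "q", kind = "binary")
  expect_setequal(res$contrast,
                  c("Q2_vs_Q1", "Q3_vs_Q1", "Q4_vs_Q1", "Q4_vs_others",
                    "trend"))
  expect_equal(res$n_used[res$contrast == "Q4_vs_Q1"], n)
  manual <- fit_logistic(transform(d, b = as.numeric(q == "Q4")), "y", "b")
  expect_equal(res$estimate[res$contrast == "Q4_vs_others"], manual$estimate,
               tolerance = 1e-10)
  # planted monotone effect shows up in the trend test
  d2 <- data.frame(q = q, y = rbinom(n, 1, plogis(-1.5 + 0.3 * as.numeric(q))))
  res2 <- quartile_contrast(d2, "y", "q", kind = "binary")
  expect_lt(res2$pvalue[res2$contrast == "trend"], 0.05)

  d3 <- d[d$q != "Q2", ]
  expect_warning(res3 <- quartile_contrast(d3, "y", "q", kind = "binary"),
                 "empty quartile")
  expect_false(res3$converged[res3$contrast == "Q2_vs_Q1"])
})

test_that("group comparisons dispatch the advertised tests", {
  # equal categorical counts: chi-square statistic 0, p = 1
  g <- rep(c("a", "b"), each = 50)
  v <- rep(c("x", "y"), 50)
  r <- group_compare(v, g, "categorical")
  expect_equal(r$method, "chi-square")
  expect_equal(r$pvalue, 1)

  set.seed(76)
  x <- c(rnorm(100), rnorm(100, 2))
  g2 <- rep(1:2, each = 100)
  expect_lt(group_compare(x, g2, "normal")$pvalue, 1e-6)
  # rank test invariant under a monotone transform
  r1 <- group_compare(x, g2, "non_normal")
  r2 <- group_compare(exp(x), g2, "non_normal")
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-12)

  g3 <- rep(1:3, each = 40)
  x3 <- rnorm(120) + 0.5 * g3
  expect_equal(group_compare(x3, g3, "normal")$method, "anova")
  expect_equal(group_compare(x3, g3, "non_normal")$method, "kruskal-wallis")
  expect_error(group_compare(1:3, c(1, 2, 2), "normal"), ">= 2")
})

test_that("the model battery covers the grid and encodes the covariate rule", {
  cfg <- simulation_config(n_individuals = 250, n_variants = 300, seed = 77)
  co <- simulate_cohort(cfg)
  qc <- run_genotype_qc(co$genotypes)
  prs <- build_prs_profiles(qc$kept_matrix, co$sumstats,
                            thresholds = c(5e-8, 0.05, 0.5))
  tab <- load_lr_table()
  kept <- co$profiles[co$profiles$individual_id %in%
                        qc$kept_matrix$individual_ids, ]
  ppd <- compute_ppd(kept, tab)
  bat <- run_model_battery(prs, ppd, kept, qc$pcs, tab)

  n_outcomes <- 5 + nrow(tab$markers) + 2 * length(cognitive_domains())
  expect_equal(nrow(bat), 3 * n_outcomes * 2)
  expect_true(all(bat$grid == "primary"))
  expect_setequal(unique(bat$covariate_set), c("standard", "fully_adjusted"))

  # pPD-derived outcomes in the standard set adjust only for the two PCs:
  # their n_used is unaffected by missing marker states
  ge30 <- bat[bat$outcome == "ppd_ge30" & bat$covariate_set == "standard", ]
  expect_true(all(ge30$n_used == nrow(ppd)))

  joint <- run_model_battery(prs, ppd, kept, qc$pcs, tab,
                             covariate_sets = "standard",
                             include_joint = TRUE)
  expect_true(any(joint$grid == "joint"))
  expect_equal(sum(joint$grid == "joint"),
               3 * 2 * length(cognitive_domains()))

  # orphan ids are reported, not silently dropped
  bad_pcs <- qc$pcs[-1, , drop = FALSE]
  expect_error(run_model_battery(prs, ppd, kept, bad_pcs, tab),
               "join failure")
})
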