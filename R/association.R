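#' Multi-adjusted logistic regression for one exposure
#'
#' Maximum-likelihood logistic fit (IRLS, gradient tolerance 1e-8, at most
#' 100 iterations) of a binary outcome on an exposure plus covariates, on
#' complete cases. The exposure effect is reported as an odds ratio with
#' Wald 95% confidence bounds `exp(b +- 1.96 SE)` and a two-sided Wald
#' p-value. Separation or non-convergence yields a row with
#' `converged = FALSE` and estimates withheld rather than misleading
#' numbers. Covariates that are constant after filtering are dropped from
#' the design; a constant exposure is an error.
#'
#' @param data data.frame holding outcome, exposure and covariates.
#' @param outcome name of a binary (0/1 or logical) column.
#' @param exposure name of the exposure column.
#' @param covariates character vector of covariate names (default empty).
#' @return one-row data.frame of class `association_result`: `outcome`,
#'   `exposure`, `kind`, `estimate` (odds ratio), `ci_low`, `ci_high`,
#'   `pvalue`, `n_used`, `converged`.
#' @export
fit_logistic <- function(data, outcome, exposure, covariates = character(0)) {
  cols <- c(outcome, exposure, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[, cols, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  y <- as.numeric(d[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1 or logical)")
  if (length(unique(y)) < 2)
    stop("outcome has a single class after filtering")
  if (var(as.numeric(d[[exposure]])) == 0)
    stop("exposure is constant: effect not identifiable")
  covariates <- covariates[vapply(covariates, function(cv) {
    v <- d[[cv]]
    if (is.numeric(v)) var(v) > 0 else length(unique(v)) > 1
  }, logical(1))]
  fml <- as.formula(paste0("`", outcome, "` ~ ",
                           paste(sprintf("`%s`", c(exposure, covariates)),
                                 collapse = " + ")))
  d[[outcome]] <- y
  fit <- suppressWarnings(glm(fml, family = binomial(), data = d,
                              control = glm.control(epsilon = 1e-8,
                                                    maxit = 100)))
  b <- coef(fit)[2]
  se <- sqrt(diag(vcov(fit)))[2]
  converged <- isTRUE(fit$converged) && is.finite(se) && se < 50
  res <- data.frame(outcome = outcome, exposure = exposure, kind = "logistic",
                    estimate = if (converged) exp(b) else NA_real_,
                    ci_low = if (converged) exp(b - 1.96 * se) else NA_real_,
                    ci_high = if (converged) exp(b + 1.96 * se) else NA_real_,
                    pvalue = if (converged)
                      2 * pnorm(-abs(b / se)) else NA_real_,
                    n_used = nrow(d), converged = converged,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("association_result", class(res))
  res
}

#' Multi-adjusted linear regression for one exposure
#'
#' Ordinary least squares of a continuous outcome on an exposure plus
#' covariates, on complete cases, with the option of a natural-log
#' transform of the outcome first (rows with non-positive outcome values
#' are dropped and counted in the `n_dropped_nonpositive` attribute). The
#' exposure coefficient is reported with its t-based 95% confidence
#' interval and two-sided p-value. A collinear design (aliased exposure
#' coefficient) is an error.
#'
#' @inheritParams fit_logistic
#' @param transform `"none"` or `"natural_log"`.
#' @return one-row `association_result` data.frame (`estimate` is the
#'   regression coefficient b).
#' @export
fit_linear <- function(data, outcome, exposure, covariates = character(0),
                       transform = c("none", "natural_log")) {
  transform <- match.arg(transform)
  cols <- c(outcome, exposure, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[, cols, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n_dropped <- 0L
  if (transform == "natural_log") {
    bad <- d[[outcome]] <= 0
    n_dropped <- sum(bad)
    d <- d[!bad, , drop = FALSE]
    d[[outcome]] <- log(d[[outcome]])
  }
  if (var(as.numeric(d[[exposure]])) == 0)
    stop("exposure is constant: effect not identifiable")
  covariates <- covariates[vapply(covariates, function(cv) {
    v <- d[[cv]]
    if (is.numeric(v)) var(v) > 0 else length(unique(v)) > 1
  }, logical(1))]
  fml <- as.formula(paste0("`", outcome, "` ~ ",
                           paste(sprintf("`%s`", c(exposure, covariates)),
                                 collapse = " + ")))
  fit <- lm(fml, data = d)
  cf <- coef(fit)
  if (anyNA(cf)) stop("collinear design: aliased coefficient(s)")
  b <- cf[2]
  sm <- summary(fit)$coefficients
  se <- sm[2, 2]; p <- sm[2, 4]
  ci <- suppressMessages(confint(fit, level = 0.95))[2, ]
  res <- data.frame(outcome = outcome, exposure = exposure, kind = "linear",
                    estimate = unname(b), ci_low = unname(ci[1]),
                    ci_high = unname(ci[2]), pvalue = unname(p),
                    n_used = nrow(d), converged = TRUE,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "n_dropped_nonpositive") <- n_dropped
  class(res) <- c("association_result", class(res))
  res
}

#' Quartile contrasts for a quartile-coded exposure
#'
#' Fits the outcome on the quartile factor (all rows kept; Q1 is the
#' reference with Q2, Q3, Q4 dummies) and reports each quartile-vs-Q1
#' contrast, the Q4-vs-{Q1,Q2,Q3} binary coding, and a trend test across
#' ordered quartile scores 1-4. Binary outcomes use logistic models (odds
#' ratios), continuous ones linear models.
#'
#' @param data data.frame.
#' @param outcome outcome column name.
#' @param quartile name of a factor/character column with levels Q1-Q4.
#' @param covariates covariate names.
#' @param kind `"binary"` or `"continuous"` outcome.
#' @return data.frame of `association_result` rows with a `contrast`
#'   column (`Q2_vs_Q1`, `Q3_vs_Q1`, `Q4_vs_Q1`, `Q4_vs_others`,
#'   `trend`). Contrasts whose quartile cell is empty are withheld
#'   (`converged = FALSE`).
#' @export
quartile_contrast <- function(data, outcome, quartile, covariates = character(0),
                              kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  q <- factor(as.character(data[[quartile]]), levels = paste0("Q", 1:4))
  rows <- list()
  fit_one <- function(d, expo) {
    if (kind == "binary") fit_logistic(d, outcome, expo, covariates)
    else fit_linear(d, outcome, expo, covariates)
  }
  empty <- setdiff(paste0("Q", 1:4), unique(as.character(q[!is.na(q)])))
  if (length(empty)) {
    warning("empty quartile cell(s): ", paste(empty, collapse = ", "),
            "; dummy contrasts withheld")
    for (lev in c("Q2", "Q3", "Q4")) {
      r <- data.frame(outcome = outcome, exposure = quartile,
                      kind = if (kind == "binary") "logistic" else "linear",
                      estimate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, pvalue = NA_real_,
                      n_used = 0L, converged = FALSE,
                      stringsAsFactors = FALSE)
      r$contrast <- paste0(lev, "_vs_Q1")
      rows[[length(rows) + 1L]] <- r
    }
  } else {
    d <- data
    for (lev in c("Q2", "Q3", "Q4")) d[[paste0("dummy_", lev)]] <-
        as.numeric(q == lev)
    for (lev in c("Q2", "Q3", "Q4")) {
      # all rows kept: the other quartile dummies enter as covariates
      others <- setdiff(c("Q2", "Q3", "Q4"), lev)
      r <- if (kind == "binary")
        fit_logistic(d, outcome, paste0("dummy_", lev),
                     c(paste0("dummy_", others), covariates))
      else fit_linear(d, outcome, paste0("dummy_", lev),
                      c(paste0("dummy_", others), covariates))
      r$contrast <- paste0(lev, "_vs_Q1")
      rows[[length(rows) + 1L]] <- r
    }
  }
  d2 <- data
  d2$q4_vs_others <- as.numeric(q == "Q4")
  r <- fit_one(d2, "q4_vs_others")
  r$contrast <- "Q4_vs_others"
  rows[[length(rows) + 1L]] <- r
  d3 <- data
  d3$trend_score <- as.numeric(q)
  r <- fit_one(d3, "trend_score")
  r$contrast <- "trend"
  rows[[length(rows) + 1L]] <- r
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", class(out))
  out
}

#' Two-group and multi-group comparisons
#'
#' Dispatches the comparison the descriptive layer uses: unpaired t-test
#' (two groups, normal), Mann-Whitney rank test (two groups, non-normal),
#' one-way ANOVA (more than two groups, normal), Kruskal-Wallis (more than
#' two, non-normal), or a chi-square test for categorical values. Normality
#' is an explicit caller decision, not assessed internally.
#'
#' @param values vector of values (categorical for `"categorical"`).
#' @param groups group labels, at least two groups.
#' @param value_kind `"normal"`, `"non_normal"` or `"categorical"`.
#' @return list with `method`, `statistic`, `pvalue`.
#' @export
group_compare <- function(values, groups,
                          value_kind = c("normal", "non_normal",
                                         "categorical")) {
  value_kind <- match.arg(value_kind)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (value_kind == "categorical") {
    tst <- suppressWarnings(chisq.test(table(values, groups), correct = FALSE))
    return(list(method = "chi-square", statistic = unname(tst$statistic),
                pvalue = tst$p.value))
  }
  sizes <- table(groups)
  if (value_kind == "normal" && any(sizes < 2))
    stop("each group needs >= 2 observations for variance-based tests")
  if (nlevels(groups) == 2) {
    if (value_kind == "normal") {
      tst <- t.test(values ~ groups)
      list(method = "t-test", statistic = unname(tst$statistic),
           pvalue = tst$p.value)
    } else {
      tst <- suppressWarnings(wilcox.test(values ~ groups))
      list(method = "mann-whitney", statistic = unname(tst$statistic),
           pvalue = tst$p.value)
    }
  } else {
    if (value_kind == "normal") {
      fit <- aov(values ~ groups)
      sm <- summary(fit)[[1]]
      list(method = "anova", statistic = sm[["F value"]][1],
           pvalue = sm[["Pr(>F)"]][1])
    } else {
      tst <- kruskal.test(values ~ groups)
      list(method = "kruskal-wallis", statistic = unname(tst$statistic),
           pvalue = tst$p.value)
    }
  }
}
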