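# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive re-implementations (loops, closed forms)
# kept separate from the package's code paths.

# chi-square HWE p-value, recomputed from first principles
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  p <- (2 * nAA + nAa) / (2 * n)
  q <- 1 - p
  e <- c(n * p^2, 2 * n * p * q, n * q^2)
  o <- c(nAA, nAa, naa)
  chi <- sum((o - e)^2 / e)
  stats::pchisq(chi, df = 1, lower.tail = FALSE)
}

# brute-force greedy clumping on a small SNP table given a dosage matrix;
# double loop, no vectorization, selection rule restated independently
oracle_clump <- function(snps, dosages, r2_max = 0.1, window_bp = 250000,
                         mhc = c(6, 27e6, 33e6)) {
  keep_region <- !(snps$chrom == mhc[1] & snps$pos >= mhc[2] &
                     snps$pos <= mhc[3])
  snps <- snps[keep_region, , drop = FALSE]
  if (nrow(snps) == 0) return(character(0))
  ord <- order(snps$pvalue, snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  selected <- character(0)
  removed <- rep(FALSE, nrow(snps))
  for (i in seq_len(nrow(snps))) {
    if (removed[i]) next
    selected <- c(selected, snps$variant_id[i])
    removed[i] <- TRUE
    for (j in seq_len(nrow(snps))) {
      if (removed[j]) next
      if (snps$chrom[j] != snps$chrom[i]) next
      if (abs(snps$pos[j] - snps$pos[i]) > window_bp) next
      xi <- dosages[, snps$variant_id[i]]
      xj <- dosages[, snps$variant_id[j]]
      xi[is.na(xi)] <- mean(xi, na.rm = TRUE)
      xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
      r <- suppressWarnings(stats::cor(xi, xj))
      if (!is.na(r) && r^2 > r2_max) removed[j] <- TRUE
    }
  }
  selected
}

# OLS coefficients by the normal equations
oracle_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# logistic MLE by hand-rolled Newton-Raphson
oracle_logistic <- function(X, y, tol = 1e-10, maxit = 50) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    grad <- t(X) %*% (y - mu)
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    b <- b + as.numeric(step)
    if (max(abs(grad)) < tol) break
  }
  list(coef = b, se = sqrt(diag(solve(H))))
}

# small genotype matrix with explicit dosages
make_gm <- function(dosages, chrom = NULL, pos = NULL, ref = NULL,
                    alt = NULL) {
  m <- ncol(dosages)
  n <- nrow(dosages)
  genotype_matrix(
    dosages,
    data.frame(variant_id = sprintf("snp%03d", seq_len(m)),
               chrom = chrom %||% rep(1L, m),
               pos = pos %||% (seq_len(m) * 1e4),
               ref = ref %||% rep("A", m),
               alt = alt %||% rep("G", m),
               stringsAsFactors = FALSE),
    sprintf("s%03d", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal marker-profile row; unspecified markers are missing
make_profile <- function(id = "p1", age = 72, sex = "male", ...,
                         table = load_lr_table()) {
  states <- list(...)
  prof <- data.frame(individual_id = id, age = age, sex = sex,
                     stringsAsFactors = FALSE)
  for (mk in table$markers$name)
    prof[[mk]] <- if (mk %in% names(states)) states[[mk]] else "missing"
  prof$pd_dlb_flag <- FALSE
  prof
}
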