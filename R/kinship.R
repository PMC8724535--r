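#' Pairwise kinship (pi-hat) by the method of moments
#'
#' PLINK-style moment estimator of the proportion of alleles shared
#' identical-by-descent for every sample pair: identity-by-state counts
#' (IBS0/1/2) are compared with their expectations under no relatedness
#' given the cohort allele frequencies, solving for P(Z=0), P(Z=1), P(Z=2)
#' and reporting `pi-hat = P(Z=1)/2 + P(Z=2)`, clamped to `[0, 1]`.
#' Monomorphic variants are ignored; missing calls drop a variant from the
#' affected pair only. No finite-sample bias correction is applied.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @return symmetric matrix of class `kinship_matrix` with pi-hat values,
#'   sample ids as dimnames, and 1 on the diagonal.
#' @export
estimate_kinship <- function(gm) {
  n <- length(gm$individual_ids)
  if (n < 2) stop("kinship estimation needs at least 2 samples")
  d <- gm$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic variants for kinship estimation")
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  q <- 1 - p

  V <- (!is.na(d)) * 1
  A0 <- (d == 0); A0[is.na(A0)] <- FALSE; A0 <- A0 * 1
  A1 <- (d == 1); A1[is.na(A1)] <- FALSE; A1 <- A1 * 1
  A2 <- (d == 2); A2[is.na(A2)] <- FALSE; A2 <- A2 * 1

  ibs2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  ibs0 <- tcrossprod(A0, A2); ibs0 <- ibs0 + t(ibs0)
  nobs <- tcrossprod(V)
  ibs1 <- nobs - ibs2 - ibs0

  # per-variant IBS expectations given IBD state Z
  e0_z0 <- 2 * p^2 * q^2
  e1_z0 <- 4 * p^3 * q + 4 * p * q^3
  e2_z0 <- 1 - e0_z0 - e1_z0
  e1_z1 <- 2 * p^2 * q + 2 * p * q^2
  e2_z1 <- 1 - e1_z1

  pairsum <- function(w) tcrossprod(sweep(V, 2, w, "*"), V)
  E0_0 <- pairsum(e0_z0)
  E1_0 <- pairsum(e1_z0)
  E2_0 <- pairsum(e2_z0)
  E1_1 <- pairsum(e1_z1)
  E2_1 <- pairsum(e2_z1)

  P0 <- ifelse(E0_0 > 0, ibs0 / E0_0, 0)
  P1 <- ifelse(E1_1 > 0, (ibs1 - P0 * E1_0) / E1_1, 0)
  P2 <- ifelse(nobs > 0, (ibs2 - P0 * E2_0 - P1 * E2_1) / nobs, 0)
  pihat <- P1 / 2 + P2
  pihat <- pmin(pmax(pihat, 0), 1)
  diag(pihat) <- 1
  dimnames(pihat) <- list(gm$individual_ids, gm$individual_ids)
  class(pihat) <- c("kinship_matrix", class(pihat))
  pihat
}

#' LD-prune variants for relatedness estimation
#'
#' Greedy pruning in position order: a variant is kept if its squared
#' dosage correlation with every already-kept variant within the window is
#' at most `r2_max`. Relatedness estimators assume (near-)independent
#' markers; running them on LD-redundant panels inflates the noise of
#' pi-hat well beyond the nominal `1/sqrt(m)`, so the QC pipeline estimates
#' kinship on this pruned subset (the PLINK-style `--indep-pairwise`
#' convention).
#'
#' @param gm a [genotype_matrix()].
#' @param r2_max maximum pairwise r-squared among kept variants.
#' @param window_kb pruning window in kilobases.
#' @param maf_min minimum minor allele frequency for a variant to enter.
#' @return character vector of kept variant ids.
#' @export
ld_prune <- function(gm, r2_max = 0.2, window_kb = 250, maf_min = 0.05) {
  v <- gm$variants
  cand <- which(variant_maf(gm) >= maf_min)
  if (!length(cand)) stop("no variants pass the MAF filter for pruning")
  ord <- cand[order(v$chrom[cand], v$pos[cand])]
  x <- imputed_dosages(gm)[, ord, drop = FALSE]
  win <- window_kb * 1000
  keep <- logical(length(ord))
  kept_idx <- integer(0)
  for (i in seq_along(ord)) {
    j <- ord[i]
    near <- kept_idx[v$chrom[ord[kept_idx]] == v$chrom[j] &
                       abs(v$pos[ord[kept_idx]] - v$pos[j]) <= win]
    ok <- TRUE
    if (length(near)) {
      r <- suppressWarnings(cor(x[, i], x[, near, drop = FALSE]))
      r[is.na(r)] <- 0
      ok <- all(r^2 <= r2_max)
    }
    if (ok) { keep[i] <- TRUE; kept_idx <- c(kept_idx, i) }
  }
  v$variant_id[ord[keep]]
}

#' Prune related samples above a kinship cutoff
#'
#' Greedy pruning: while any pair exceeds the cutoff, take the pair with the
#' largest kinship (ties broken by sample id) and remove the member with the
#' higher genotype missingness, breaking ties towards the lexicographically
#' larger id. Guarantees no retained pair exceeds the cutoff.
#'
#' @param kinship a symmetric [estimate_kinship()] matrix.
#' @param cutoff pi-hat above which a pair is considered related
#'   (default 0.125, the third-degree-relative bound).
#' @param missingness optional named per-sample missingness used to choose
#'   which member of a pair to drop; defaults to zero for all.
#' @return character vector of excluded sample ids (possibly empty).
#' @export
kinship_filter <- function(kinship, cutoff = 0.125, missingness = NULL) {
  k <- unclass(kinship)
  ids <- rownames(k)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(k)))
  if (max(abs(k - t(k))) > 1e-8) stop("kinship matrix must be symmetric")
  k <- (k + t(k)) / 2  # remove floating-point asymmetry from BLAS products
  if (is.null(missingness)) missingness <- setNames(numeric(length(ids)), ids)
  miss <- if (is.null(names(missingness))) setNames(numeric(length(ids)), ids)
          else missingness[ids]
  miss[is.na(miss)] <- 0
  names(miss) <- ids

  diag(k) <- 0
  removed <- character(0)
  repeat {
    k_active <- k
    if (length(removed)) {
      ridx <- match(removed, ids)
      k_active[ridx, ] <- 0
      k_active[, ridx] <- 0
    }
    mx <- max(k_active)
    if (mx <= cutoff) break
    cand <- which(k_active == mx, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_ids <- cbind(ids[cand[, 1]], ids[cand[, 2]])
    ord <- order(pair_ids[, 1], pair_ids[, 2])
    a <- pair_ids[ord[1], 1]; b <- pair_ids[ord[1], 2]
    drop_id <- if (miss[a] > miss[b]) a
    else if (miss[b] > miss[a]) b
    else max(a, b)
    removed <- c(removed, drop_id)
  }
  removed
}
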