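#' Default p-value threshold set for clumping + thresholding scores
#'
#' The a-priori thresholds 1e-4, 0.001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5 plus
#' the genome-wide significance tier 5e-8.
#' @export
default_thresholds <- function() {
  c(5e-8, 1e-4, 0.001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
}

#' Clumping parameters
#'
#' @param r2_max maximum pairwise LD (squared Pearson correlation of
#'   mean-imputed dosages in the target cohort) tolerated between retained
#'   SNPs within a window.
#' @param window_kb half-window in kilobases: SNPs within +-`window_kb` of
#'   an index SNP on the same chromosome compete with it.
#' @param excluded_regions list of `c(chrom, start_bp, end_bp)` triples
#'   removed before clumping; the default is the extended MHC
#'   (chr6:27-33 Mb, hg19), inclusive at both ends.
#' @return list of class `clump_params`.
#' @export
clump_params <- function(r2_max = 0.1, window_kb = 250,
                         excluded_regions = list(c(6, 27e6, 33e6))) {
  if (r2_max <= 0 || r2_max >= 1) stop("r2_max must be in (0,1)")
  if (window_kb <= 0) stop("window_kb must be positive")
  structure(list(r2_max = r2_max, window_kb = window_kb,
                 excluded_regions = excluded_regions),
            class = "clump_params")
}

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

#' Harmonize summary statistics to a target variant panel
#'
#' Matches records by (chrom, pos) and reconciles alleles so every retained
#' effect size refers to the target ALT allele: a direct match keeps the
#' effect, a swapped match (effect allele = target REF) negates it, and a
#' strand-flipped match is complemented first and then the swap rule
#' applied. Strand-ambiguous variants (A/T, C/G) that can only be matched
#' by flipping are dropped and counted, as are positions absent from either
#' side.
#'
#' @param variants the `variants` table of a [genotype_matrix()] (post-QC:
#'   duplicate positions are an error here, not handled).
#' @param sumstats data.frame with `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `pvalue`.
#' @return data.frame with `variant_id`, `chrom`, `pos`, `beta` (target
#'   ALT convention), `pvalue`, plus a `match_counts` attribute.
#' @export
harmonize_sumstats <- function(variants, sumstats) {
  key_t <- paste(variants$chrom, variants$pos)
  key_s <- paste(sumstats$chrom, sumstats$pos)
  if (anyDuplicated(key_t)) stop("duplicate positions in target variants; run variant QC first")
  if (anyDuplicated(key_s)) stop("duplicate positions in summary statistics")
  idx <- match(key_t, key_s)
  counts <- c(direct = 0L, swapped = 0L, flipped = 0L,
              ambiguous_dropped = 0L, unmatched = sum(is.na(idx)))
  rows <- list()
  for (i in which(!is.na(idx))) {
    s <- sumstats[idx[i], ]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    ea <- s$effect_allele; oa <- s$other_allele
    amb <- is_ambiguous(ref, alt)
    beta <- NA_real_
    if (ea == alt && oa == ref) {
      beta <- s$beta; counts["direct"] <- counts["direct"] + 1L
    } else if (ea == ref && oa == alt) {
      beta <- -s$beta; counts["swapped"] <- counts["swapped"] + 1L
    } else if (!amb && complement_allele(ea) == alt &&
               complement_allele(oa) == ref) {
      beta <- s$beta; counts["flipped"] <- counts["flipped"] + 1L
    } else if (!amb && complement_allele(ea) == ref &&
               complement_allele(oa) == alt) {
      beta <- -s$beta; counts["flipped"] <- counts["flipped"] + 1L
    } else if (amb) {
      counts["ambiguous_dropped"] <- counts["ambiguous_dropped"] + 1L
      next
    } else {
      counts["unmatched"] <- counts["unmatched"] + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = variants$variant_id[i], chrom = variants$chrom[i],
      pos = variants$pos[i], beta = beta, pvalue = s$pvalue,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(0), chrom = integer(0),
               pos = numeric(0), beta = numeric(0), pvalue = numeric(0))
  attr(out, "match_counts") <- counts
  out
}

#' Filter target variants for scoring
#'
#' Keeps variants strictly exceeding all three bounds (minor allele
#' frequency, call rate, imputation quality); values exactly on a bound are
#' excluded. Variants without an imputation quality score carry the
#' genotyped-variant default 1.0 and therefore pass.
#'
#' @param variants a `variants` table with `maf`, `call_rate`, `info_score`.
#' @param maf_min,call_rate_min,info_min the strict lower bounds.
#' @return the retained rows of `variants`.
#' @export
filter_target_variants <- function(variants, maf_min = 0.05,
                                   call_rate_min = 0.95, info_min = 0.4) {
  info <- variants$info_score
  if (is.null(info)) info <- rep(1.0, nrow(variants))
  info[is.na(info)] <- 1.0
  keep <- variants$maf > maf_min & variants$call_rate > call_rate_min &
    info > info_min
  variants[keep, , drop = FALSE]
}

in_excluded_region <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(chrom))
  for (r in regions)
    hit <- hit | (chrom == r[1] & pos >= r[2] & pos <= r[3])
  hit
}

#' Greedy LD clumping
#'
#' Sorts candidate SNPs by ascending p-value (ties by chromosome then
#' position), repeatedly takes the best remaining SNP as an index SNP and
#' removes every remaining SNP on the same chromosome within
#' +-`window_kb` whose squared dosage correlation with it exceeds
#' `r2_max`. Variants inside `excluded_regions` (default: the MHC) are
#' removed before clumping. LD is computed from mean-imputed dosages of the
#' target cohort.
#'
#' @param harmonized output of [harmonize_sumstats()] (or any data.frame
#'   with `variant_id`, `chrom`, `pos`, `pvalue`).
#' @param gm the target [genotype_matrix()] containing those variants.
#' @param params a [clump_params()].
#' @return the index-SNP rows of `harmonized`, in selection order.
#' @export
clump_variants <- function(harmonized, gm, params = clump_params()) {
  if (nrow(harmonized) == 0) return(harmonized)
  h <- harmonized[!in_excluded_region(harmonized$chrom, harmonized$pos,
                                      params$excluded_regions), , drop = FALSE]
  if (nrow(h) == 0) return(h)
  h <- h[order(h$pvalue, h$chrom, h$pos), , drop = FALSE]
  cols <- match(h$variant_id, gm$variants$variant_id)
  if (anyNA(cols)) stop("clump candidates missing from genotype matrix")
  x <- imputed_dosages(gm)[, cols, drop = FALSE]

  n <- nrow(h)
  alive <- rep(TRUE, n)
  picked <- integer(0)
  win <- params$window_kb * 1000
  for (i in seq_len(n)) {
    if (!alive[i]) next
    picked <- c(picked, i)
    cand <- which(alive & seq_len(n) > i & h$chrom == h$chrom[i] &
                    abs(h$pos - h$pos[i]) <= win)
    if (length(cand)) {
      r <- suppressWarnings(cor(x[, i], x[, cand, drop = FALSE]))
      r[is.na(r)] <- 0
      alive[cand[r^2 > params$r2_max]] <- FALSE
    }
    alive[i] <- FALSE
  }
  h[picked, , drop = FALSE]
}

#' Select clumped SNPs below a p-value threshold
#'
#' Strict comparison (`pvalue < threshold`), so selections are nested
#' across an increasing threshold sequence.
#'
#' @param clumped output of [clump_variants()].
#' @param threshold p-value cutoff.
#' @return the subset of `clumped` passing the threshold.
#' @export
select_by_threshold <- function(clumped, threshold) {
  clumped[clumped$pvalue < threshold, , drop = FALSE]
}

#' Weighted-allele polygenic score
#'
#' `score_i = sum_j beta_j * dosage_ij` over the selected SNPs, with a
#' missing dosage replaced by the variant's mean observed dosage (twice the
#' alternate-allele frequency). Betas must already be harmonized to the
#' matrix's ALT-allele convention.
#'
#' @param gm a [genotype_matrix()].
#' @param snps data.frame with `variant_id` and `beta`.
#' @param standardize if `TRUE`, scores are z-standardized across the
#'   cohort; raw weighted sums are the default.
#' @return named numeric vector of per-individual scores.
#' @export
prs_score <- function(gm, snps, standardize = FALSE) {
  if (nrow(snps) == 0)
    return(setNames(numeric(length(gm$individual_ids)), gm$individual_ids))
  cols <- match(snps$variant_id, gm$variants$variant_id)
  if (anyNA(cols))
    stop("SNP(s) absent from genotype matrix: ",
         paste(head(snps$variant_id[is.na(cols)]), collapse = ", "))
  x <- imputed_dosages(gm)[, cols, drop = FALSE]
  s <- as.numeric(x %*% snps$beta)
  if (standardize) s <- as.numeric(scale(s))
  setNames(s, gm$individual_ids)
}

#' Quartile labels for a score vector
#'
#' Sample quartiles with boundaries at the 25/50/75 percentiles
#' (linear-interpolation definition); a value tied with a boundary is
#' assigned to the lower quartile. Q4 is the top quartile.
#'
#' @param scores numeric vector, length >= 4.
#' @return factor with levels Q1-Q4.
#' @export
quartilize <- function(scores) {
  if (length(scores) < 4) stop("quartiles need at least 4 values")
  qs <- quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lab <- 1L + (scores > qs[1]) + (scores > qs[2]) + (scores > qs[3])
  if (length(unique(lab)) == 1L)
    warning("degenerate scores: all values in one quartile")
  factor(paste0("Q", lab), levels = paste0("Q", 1:4))
}

#' Build polygenic score profiles across a threshold set
#'
#' Runs harmonization, the target-variant filter, MHC exclusion and greedy
#' clumping once, then scores every individual at each p-value threshold
#' and attaches cohort quartile labels per threshold.
#'
#' @param gm the post-QC target [genotype_matrix()].
#' @param sumstats discovery summary statistics (see
#'   [harmonize_sumstats()]).
#' @param thresholds increasing p-value cutoffs.
#' @param params a [clump_params()].
#' @param maf_min,call_rate_min,info_min scoring filters applied to the
#'   target panel before clumping.
#' @return data.frame of class `prs_profiles` in long format:
#'   `individual_id`, `threshold`, `score`, `quartile`, `n_snps`; the
#'   clumped SNP table is attached as attribute `clumped`.
#' @export
build_prs_profiles <- function(gm, sumstats, thresholds = default_thresholds(),
                               params = clump_params(), maf_min = 0.05,
                               call_rate_min = 0.95, info_min = 0.4) {
  thresholds <- sort(thresholds)
  kept <- filter_target_variants(gm$variants, maf_min, call_rate_min, info_min)
  gmf <- subset_genotypes(gm, variants = kept$variant_id)
  harm <- harmonize_sumstats(gmf$variants, sumstats)
  clumped <- clump_variants(harm, gmf, params)
  out <- do.call(rbind, lapply(thresholds, function(th) {
    sel <- select_by_threshold(clumped, th)
    sc <- prs_score(gmf, sel)
    data.frame(individual_id = names(sc), threshold = th, score = sc,
               quartile = if (length(sc) >= 4 && sd(sc) > 0) quartilize(sc)
                          else factor(rep("Q1", length(sc)),
                                      levels = paste0("Q", 1:4)),
               n_snps = nrow(sel), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  attr(out, "clumped") <- clumped
  attr(out, "match_counts") <- attr(harm, "match_counts")
  class(out) <- c("prs_profiles", class(out))
  out
}
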