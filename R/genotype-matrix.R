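#' Genotype matrix container
#'
#' Bundles an individuals-by-variants dosage matrix (values 0/1/2, `NA` for a
#' missing call) with per-variant metadata. This is the substrate for quality
#' control, LD computation and polygenic scoring.
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param variants data.frame with one row per variant and columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, and optionally `maf`,
#'   `call_rate`, `info_score` (recomputed / defaulted when absent).
#' @param individual_ids character vector of unique sample identifiers.
#' @param genome_build coordinate build label carried as metadata.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `individual_ids`, `genome_build`.
#' @export
genotype_matrix <- function(dosages, variants, individual_ids,
                            genome_build = "hg19") {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("dosages must be numeric")
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (length(individual_ids) != nrow(dosages))
    stop("individual_ids length does not match dosage rows")
  if (anyDuplicated(individual_ids))
    stop("individual_ids must be unique")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("variants rows do not match dosage columns")
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt)) ||
      any(variants$ref == variants$alt))
    stop("alleles must be non-empty and distinct")
  rownames(dosages) <- individual_ids
  colnames(dosages) <- variants$variant_id
  gm <- structure(list(dosages = dosages, variants = variants,
                       individual_ids = as.character(individual_ids),
                       genome_build = genome_build),
                  class = "genotype_matrix")
  gm$variants$call_rate <- variant_call_rate(gm)
  gm$variants$maf <- variant_maf(gm)
  if (is.null(variants$info_score)) gm$variants$info_score <- 1.0
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%s)\n",
              nrow(x$dosages), ncol(x$dosages), x$genome_build))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Per-variant alternate-allele frequency, minor-allele frequency, call rate
#'
#' Frequencies are computed from the non-missing dosages currently in the
#' matrix, so they always refer to the analysis cohort at hand.
#'
#' @param gm a [genotype_matrix()].
#' @return numeric vector, one entry per variant.
#' @export
variant_alt_freq <- function(gm) {
  colMeans(gm$dosages, na.rm = TRUE) / 2
}

#' @rdname variant_alt_freq
#' @export
variant_maf <- function(gm) {
  p <- variant_alt_freq(gm)
  pmin(p, 1 - p)
}

#' @rdname variant_alt_freq
#' @export
variant_call_rate <- function(gm) {
  colMeans(!is.na(gm$dosages))
}

#' Per-variant missingness within the full matrix or a sample subset
#' @keywords internal
variant_missingness <- function(gm, rows = NULL) {
  d <- if (is.null(rows)) gm$dosages else gm$dosages[rows, , drop = FALSE]
  colMeans(is.na(d))
}

#' Subset a genotype matrix by individuals and/or variants
#'
#' @param gm a [genotype_matrix()].
#' @param individuals character ids or logical/integer index; default all.
#' @param variants character variant ids or logical/integer index; default all.
#' @return a `genotype_matrix` with `maf` and `call_rate` recomputed on the
#'   retained individuals.
#' @export
subset_genotypes <- function(gm, individuals = NULL, variants = NULL) {
  ri <- seq_along(gm$individual_ids)
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) {
      match(individuals, gm$individual_ids)
    } else which(rep(TRUE, length(ri)))[individuals]
    if (anyNA(ri)) stop("unknown individual id(s)")
  }
  ci <- seq_len(nrow(gm$variants))
  if (!is.null(variants)) {
    ci <- if (is.character(variants)) {
      match(variants, gm$variants$variant_id)
    } else which(rep(TRUE, length(ci)))[variants]
    if (anyNA(ci)) stop("unknown variant id(s)")
  }
  info <- gm$variants$info_score[ci]
  out <- genotype_matrix(gm$dosages[ri, ci, drop = FALSE],
                         gm$variants[ci, , drop = FALSE],
                         gm$individual_ids[ri],
                         genome_build = gm$genome_build)
  out$variants$info_score <- info
  out
}

#' Mean-imputed dosage matrix
#'
#' Missing calls are replaced by the variant's mean observed dosage
#' (twice the alternate-allele frequency), the convention used both for LD
#' computation and for polygenic scoring.
#' @keywords internal
imputed_dosages <- function(gm) {
  d <- gm$dosages
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  d
}
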