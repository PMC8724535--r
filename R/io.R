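#' Write and read the TSV dosage matrix
#'
#' Rows are variants (metadata columns first), columns are individuals.
#' Missing dosages are written as the token `NA`. The writer/reader pair
#' round-trips a [genotype_matrix()] exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(gm, path) {
  dt <- data.table::as.data.table(gm$variants[, c("variant_id", "chrom",
                                                  "pos", "ref", "alt",
                                                  "info_score")])
  geno <- data.table::as.data.table(t(gm$dosages))
  data.table::setnames(geno, gm$individual_ids)
  data.table::fwrite(cbind(dt, geno), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "info_score")
  miss <- setdiff(meta_cols, names(dt))
  if (length(miss)) stop("dosage TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  ids <- setdiff(names(dt), meta_cols)
  d <- t(as.matrix(dt[, ids, with = FALSE]))
  storage.mode(d) <- "double"
  variants <- as.data.frame(dt[, meta_cols, with = FALSE])
  gm <- genotype_matrix(d, variants[, c("variant_id", "chrom", "pos",
                                        "ref", "alt")], ids)
  gm$variants$info_score <- variants$info_score
  gm
}

#' Write a genotype matrix as an unphased VCF
#'
#' Biallelic records with GT fields (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param gm a [genotype_matrix()].
#' @param path output file (plain text, VCF 4.2).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$dosages), ncol(gm$dosages))
  obs <- !is.na(gm$dosages)
  gt[obs] <- gtmap[gm$dosages[obs] + 1]
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##reference=%s", gm$genome_build),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individual_ids), collapse = "\t"),
    paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
          v$variant_id, v$ref, v$alt, ".", "PASS", ".", "GT",
          apply(gt, 2, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from VCF or TSV dosage matrix
#'
#' VCF GT fields are mapped to the dosage of the ALT allele (`0/0` -> 0,
#' `0/1` -> 1, `1/1` -> 2, `./.` -> missing; phased separators are
#' accepted). Multi-allelic records are rejected and counted in the
#' `n_multiallelic_dropped` attribute.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dosage_tsv") return(read_dosage_tsv(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    ifelse(g %in% c("0/0"), 0,
           ifelse(g %in% c("0/1", "1/0"), 1,
                  ifelse(g %in% c("1/1"), 2, NA_real_)))
  }
  d <- code(gt)
  dim(d) <- dim(gt)
  d <- t(d)
  ids <- colnames(gt)
  variants <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = suppressWarnings(ifelse(grepl("^[0-9]+$", fix$CHROM),
                                    as.integer(fix$CHROM), fix$CHROM)),
    pos = as.numeric(fix$POS), ref = fix$REF, alt = fix$ALT,
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(d, variants, ids)
  attr(gm, "n_multiallelic_dropped") <- n_multi
  gm
}

#' Write / read discovery summary statistics
#'
#' TSV with header `chrom, pos, ref, alt, effect_allele, other_allele,
#' beta, se, pvalue, maf`. The reader validates the header and names any
#' missing column.
#'
#' @param sumstats data.frame as produced by [simulate_summary_stats()].
#' @param path file path.
#' @export
write_sumstats_tsv <- function(sumstats, path) {
  data.table::fwrite(sumstats, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  req <- c("chrom", "pos", "effect_allele", "other_allele", "beta", "pvalue")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("summary statistics missing column(s): ",
                         paste(miss, collapse = ", "))
  as.data.frame(dt)
}

#' Write / read marker profiles
#'
#' One row per individual; marker columns carry the tokens
#' `present`/`absent`/`missing`.
#'
#' @param profiles marker-profile data.frame.
#' @param path file path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  data.table::fwrite(profiles, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  req <- c("individual_id", "age", "sex")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("marker profiles missing column(s): ",
                         paste(miss, collapse = ", "))
  as.data.frame(dt)
}

#' Write a truth log of injected QC failures to JSON
#' @param truth_log the `truth_log` of a [inject_qc_failures()] cohort.
#' @param path file path.
#' @export
write_truth_log_json <- function(truth_log, path) {
  jsonlite::write_json(truth_log, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
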