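#' Likelihood-ratio table for the prodromal-PD calculator
#'
#' The MDS research criteria score each risk and prodromal marker with a
#' positive likelihood ratio (applied when the marker is present) and a
#' negative one (applied when absent); a missing marker contributes 1.0.
#' Age-specific pretest probabilities complete the calculator. The package
#' ships a default table (`inst/extdata/mds_lr_table.yaml`) populated from
#' the 2019 MDS research criteria; it is an editable configuration, not code
#' — swap in your own values with `load_lr_table()`.
#'
#' @param path YAML file; defaults to the table shipped with the package.
#' @return An object of class `lr_table`: list with `markers` (data.frame
#'   `name`, `class`, `lr_positive`, `lr_negative`), `age_priors` (data.frame
#'   `age_min`, `age_max`, `prior`; bands are half-open `[min, max)`),
#'   `prs_quartile_scheme` (named numeric, Q1..Q4), `version`, and `hash`
#'   (md5 of the source file, logged by the pipeline for provenance).
#' @export
load_lr_table <- function(path = system.file("extdata", "mds_lr_table.yaml",
                                             package = "prodromalPRS")) {
  if (!file.exists(path)) stop("LR table file not found: ", path)
  raw <- yaml::read_yaml(path)
  markers <- do.call(rbind, lapply(raw$markers, function(m)
    data.frame(name = m$name, class = m$class,
               lr_positive = as.numeric(m$lr_positive),
               lr_negative = as.numeric(m$lr_negative),
               stringsAsFactors = FALSE)))
  age_priors <- do.call(rbind, lapply(raw$age_priors, function(b)
    data.frame(age_min = as.numeric(b$age_min),
               age_max = as.numeric(b$age_max),
               prior = as.numeric(b$prior))))
  age_priors <- age_priors[order(age_priors$age_min), ]
  tab <- structure(list(
    markers = markers,
    age_priors = age_priors,
    prs_quartile_scheme = unlist(raw$prs_quartile_scheme),
    version = raw$version %||% "unversioned",
    hash = unname(tools::md5sum(path))
  ), class = "lr_table")
  validate_lr_table(tab)
  tab
}

validate_lr_table <- function(tab) {
  m <- tab$markers
  if (anyDuplicated(m$name)) stop("duplicate marker names in LR table")
  if (!all(m$class %in% c("risk", "prodromal")))
    stop("marker class must be 'risk' or 'prodromal'")
  if (any(m$lr_positive <= 0) || any(m$lr_negative <= 0))
    stop("all likelihood ratios must be positive")
  ap <- tab$age_priors
  if (any(ap$prior <= 0 | ap$prior >= 1))
    stop("age priors must be probabilities in (0,1)")
  if (any(ap$age_min >= ap$age_max)) stop("malformed age band")
  if (nrow(ap) > 1 && any(ap$age_min[-1] != ap$age_max[-nrow(ap)]))
    stop("age bands must partition [min_age, Inf) without gaps")
  sch <- tab$prs_quartile_scheme
  if (!all(c("Q1", "Q2", "Q3", "Q4") %in% names(sch)))
    stop("prs_quartile_scheme must name Q1..Q4")
  invisible(tab)
}

#' @export
print.lr_table <- function(x, ...) {
  cat(sprintf("lr_table '%s' (%d risk, %d prodromal markers, %d age bands)\n",
              x$version, sum(x$markers$class == "risk"),
              sum(x$markers$class == "prodromal"), nrow(x$age_priors)))
  invisible(x)
}

#' Marker names of a given class
#' @param table an [load_lr_table()] object.
#' @param class `"risk"`, `"prodromal"`, or `"all"`.
#' @export
lr_marker_names <- function(table, class = c("all", "risk", "prodromal")) {
  class <- match.arg(class)
  m <- table$markers
  if (class == "all") m$name else m$name[m$class == class]
}

#' Pretest probability of prodromal PD for a given age
#'
#' Looks up the age-band prior. Bands are half-open `[age_min, age_max)`, so
#' an age exactly on a boundary belongs to the upper band; the last band is
#' open-ended. Ages below the first band are an error rather than silently
#' extrapolated.
#'
#' @param age numeric vector of ages in years.
#' @param table an [load_lr_table()] object.
#' @return numeric vector of pretest probabilities.
#' @export
pretest_probability <- function(age, table) {
  ap <- table$age_priors
  if (any(age < ap$age_min[1]))
    stop("age out of range: below the minimum age band (",
         ap$age_min[1], ")")
  band <- findInterval(age, ap$age_min)  # [lo, hi) by construction
  ap$prior[band]
}
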