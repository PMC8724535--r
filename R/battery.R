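#' Assemble the per-individual analysis frame
#'
#' Joins, by individual id, the pPD results (which define the analysis
#' cohort), the marker profiles, the genetic principal components and —
#' per threshold — the polygenic scores. Ids present in the pPD results
#' but missing from any other member are an error, listed explicitly.
#'
#' @param ppd a [compute_ppd()] result.
#' @param profiles the marker-profile data.frame.
#' @param pcs principal-component matrix with MDSC1/MDSC2 columns and ids
#'   as rownames.
#' @return data.frame keyed by `individual_id` with covariates, marker
#'   indicators (1 = present, 0 = absent, NA = missing), cognitive
#'   z-scores, per-domain deficit indicators (z <= -1), flags and pPD
#'   quantities.
#' @export
assemble_analysis_frame <- function(ppd, profiles, pcs) {
  ids <- ppd$individual_id
  orphan <- function(have, what) {
    bad <- setdiff(ids, have)
    if (length(bad))
      stop("join failure: ids missing from ", what, ": ",
           paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  }
  orphan(profiles$individual_id, "marker profiles")
  orphan(rownames(pcs), "principal components")
  pr <- profiles[match(ids, profiles$individual_id), , drop = FALSE]
  fr <- data.frame(individual_id = ids,
                   MDSC1 = pcs[ids, "MDSC1"], MDSC2 = pcs[ids, "MDSC2"],
                   age = pr$age,
                   sex_female = as.numeric(pr$sex == "female"),
                   stringsAsFactors = FALSE)
  state_cols <- setdiff(names(pr)[vapply(pr, function(x)
    is.character(x) && all(x %in% c("present", "absent", "missing")),
    logical(1))], "sex")
  for (mk in state_cols)
    fr[[mk]] <- ifelse(pr[[mk]] == "present", 1,
                       ifelse(pr[[mk]] == "absent", 0, NA))
  for (z in grep("^z_", names(pr), value = TRUE)) {
    fr[[z]] <- pr[[z]]
    fr[[sub("^z_", "deficit_", z)]] <- as.numeric(pr[[z]] <= -1)
  }
  for (fl in intersect(c("dementia_flag", "mci_flag"), names(pr)))
    fr[[fl]] <- pr[[fl]]
  fr$ppd_posttest <- ppd$posttest
  fr$risk_lr <- ppd$risk_lr
  fr$prodromal_lr <- ppd$prodromal_lr
  fr$ppd_ge30 <- as.numeric(ppd$ge30)
  fr$ppd_ge50 <- as.numeric(ppd$ge50)
  rownames(fr) <- NULL
  fr
}

battery_subset <- function(fr, subset) {
  switch(subset,
    all = fr,
    no_dementia = fr[!(fr$dementia_flag %||% FALSE), , drop = FALSE],
    no_dementia_mci = fr[!(fr$dementia_flag | fr$mci_flag), , drop = FALSE],
    fdr_present = fr[!is.na(fr$first_degree_relative_pd) &
                       fr$first_degree_relative_pd == 1, , drop = FALSE],
    fdr_absent = fr[!is.na(fr$first_degree_relative_pd) &
                      fr$first_degree_relative_pd == 0, , drop = FALSE],
    stop("unknown subset: ", subset))
}

withheld_row <- function(outcome, kind, msg) {
  data.frame(outcome = outcome, exposure = "prs", kind = kind,
             estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             pvalue = NA_real_, n_used = 0L, converged = FALSE,
             note = msg, stringsAsFactors = FALSE)
}

#' Run the full association model battery
#'
#' Executes the model grid of the analysis: for every p-value threshold and
#' covariate set, the polygenic score (continuous) is regressed against the
#' pPD probability (natural-log-transformed, linear), the 30% and 50%
#' dichotomizations (logistic), the log total risk and prodromal likelihood
#' ratios (linear), every configured risk and prodromal marker (logistic),
#' and each cognitive-domain z-score (linear) and deficit indicator
#' (logistic). Joint cognitive models (all domains in one fit, score as
#' outcome) are appended when `include_joint = TRUE`.
#'
#' The `"standard"` covariate set adjusts marker and cognition models for
#' MDSC1, MDSC2, age and sex, but pPD-derived outcomes (probability, LRs,
#' cut-offs) for MDSC1 and MDSC2 only, because those outcomes already
#' encode age and sex. The `"fully_adjusted"` set uses all four covariates
#' everywhere (exploratory). A model whose outcome encodes sex drops the
#' sex covariate. Fits that fail (single-class outcome in a small subset,
#' constant exposure) are reported as withheld rows, not dropped silently.
#'
#' @param prs a [build_prs_profiles()] result.
#' @param ppd a [compute_ppd()] result.
#' @param profiles marker profiles.
#' @param pcs principal components (MDSC1/MDSC2).
#' @param table an [load_lr_table()] object naming the markers.
#' @param covariate_sets subset of `c("standard", "fully_adjusted")`.
#' @param subset `"all"`, `"no_dementia"`, `"no_dementia_mci"`,
#'   `"fdr_present"` or `"fdr_absent"`.
#' @param include_joint append the joint cognitive models.
#' @return data.frame: one association row per (threshold, covariate set,
#'   outcome), columns as [fit_logistic()] plus `threshold`,
#'   `covariate_set`, `outcome_class`, `grid`, `subset`, `note`.
#' @export
run_model_battery <- function(prs, ppd, profiles, pcs,
                              table = load_lr_table(),
                              covariate_sets = c("standard", "fully_adjusted"),
                              subset = "all", include_joint = FALSE) {
  fr0 <- assemble_analysis_frame(ppd, profiles, pcs)
  fr0 <- battery_subset(fr0, subset)
  thresholds <- sort(unique(prs$threshold))
  markers <- intersect(table$markers$name, names(fr0))
  domains <- grep("^z_", names(fr0), value = TRUE)
  deficits <- sub("^z_", "deficit_", domains)

  outcomes <- rbind(
    data.frame(outcome = "ppd_posttest", kind = "linear", transform = "natural_log",
               class = "ppd", stringsAsFactors = FALSE),
    data.frame(outcome = c("ppd_ge30", "ppd_ge50"), kind = "logistic",
               transform = "none", class = "ppd"),
    data.frame(outcome = c("risk_lr", "prodromal_lr"), kind = "linear",
               transform = "natural_log", class = "ppd"),
    data.frame(outcome = markers, kind = "logistic", transform = "none",
               class = "marker"),
    data.frame(outcome = domains, kind = "linear", transform = "none",
               class = "cognition"),
    data.frame(outcome = deficits, kind = "logistic", transform = "none",
               class = "cognition"))

  rows <- list()
  for (th in thresholds) {
    sc <- prs[prs$threshold == th, ]
    fr <- fr0
    fr$prs <- sc$score[match(fr$individual_id, sc$individual_id)]
    if (anyNA(fr$prs))
      stop("join failure: ids missing from PRS profiles: ",
           paste(head(fr$individual_id[is.na(fr$prs)], 10), collapse = ", "))
    for (cs in covariate_sets) {
      for (i in seq_len(nrow(outcomes))) {
        oc <- outcomes$outcome[i]
        covs <- if (cs == "standard" && outcomes$class[i] == "ppd")
          c("MDSC1", "MDSC2")
        else c("MDSC1", "MDSC2", "age", "sex_female")
        if (oc %in% c("male_sex", "erectile_dysfunction"))
          covs <- setdiff(covs, "sex_female")
        r <- tryCatch({
          if (outcomes$kind[i] == "logistic")
            fit_logistic(fr, oc, "prs", covs)
          else fit_linear(fr, oc, "prs", covs,
                          transform = outcomes$transform[i])
        }, error = function(e)
          withheld_row(oc, outcomes$kind[i], conditionMessage(e)))
        if (is.null(r$note)) r$note <- ""
        r$threshold <- th
        r$covariate_set <- cs
        r$outcome_class <- outcomes$class[i]
        r$grid <- "primary"
        r$subset <- subset
        rows[[length(rows) + 1L]] <- r
      }
      if (include_joint) {
        # joint models: score as outcome, all domains (or all deficit
        # indicators) entering one fit; each exposure reported in turn
        for (joint_cols in list(domains, deficits)) {
          covs <- c("MDSC1", "MDSC2", "age", "sex_female")
          for (cc in joint_cols) {
            r <- tryCatch(
              fit_linear(fr, "prs", cc, c(setdiff(joint_cols, cc), covs)),
              error = function(e) withheld_row(cc, "linear",
                                               conditionMessage(e)))
            if (is.null(r$note)) r$note <- ""
            r$outcome <- "prs"; r$exposure <- cc
            r$threshold <- th; r$covariate_set <- cs
            r$outcome_class <- "cognition"
            r$grid <- "joint"; r$subset <- subset
            rows[[length(rows) + 1L]] <- r
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Most associated marker in a battery result
#'
#' Among the primary-grid marker models at one threshold and covariate
#' set, returns the marker with the smallest p-value.
#'
#' @param battery a [run_model_battery()] result.
#' @param threshold the PRS threshold to inspect.
#' @param covariate_set which covariate set's rows to use.
#' @return named numeric: the minimum p-value, named by its marker.
#' @export
most_associated_marker <- function(battery, threshold = 5e-8,
                                   covariate_set = "standard") {
  b <- battery[battery$grid == "primary" &
                 battery$outcome_class == "marker" &
                 battery$covariate_set == covariate_set &
                 abs(battery$threshold - threshold) < 1e-15 &
                 !is.na(battery$pvalue), ]
  if (nrow(b) == 0) stop("no marker rows at that threshold")
  i <- which.min(b$pvalue)
  setNames(b$pvalue[i], b$outcome[i])
}
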