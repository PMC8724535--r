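#' Likelihood ratio contributed by one marker state
#'
#' Present markers contribute their positive LR, absent markers their
#' negative LR, and missing markers contribute exactly 1.0 (the
#' missing-information convention of the research criteria, which leaves
#' the running odds unchanged).
#'
#' @param state character vector of `"present"`, `"absent"`, `"missing"`.
#' @param marker marker name (must exist in the table).
#' @param table an [load_lr_table()] object.
#' @return numeric vector of likelihood ratios.
#' @export
marker_lr <- function(state, marker, table) {
  row <- table$markers[table$markers$name == marker, ]
  if (nrow(row) != 1) stop("unknown marker: ", marker)
  bad <- !state %in% c("present", "absent", "missing")
  if (any(bad)) stop("invalid marker state(s): ",
                     paste(unique(state[bad]), collapse = ", "))
  ifelse(state == "present", row$lr_positive,
         ifelse(state == "absent", row$lr_negative, 1.0))
}

#' Total risk, prodromal and combined likelihood ratios for profiles
#'
#' Multiplies marker LRs within the risk class and within the prodromal
#' class, then multiplies the two products into the total LR. A profile
#' with every marker missing therefore has total LR exactly 1. Markers
#' listed in `drop` are forced to contribute 1.0 for everyone (the
#' marker-exclusion sensitivity analysis); `substitute_lr` overrides one
#' marker's contribution with an externally supplied per-individual LR
#' (the PRS-quartile sensitivity analysis).
#'
#' @param profiles marker-profile data.frame (one row per individual, one
#'   column per marker with present/absent/missing states).
#' @param table an [load_lr_table()] object.
#' @param drop character vector of marker names to neutralize.
#' @param substitute_lr optional list `list(marker = name, lr = numeric
#'   per-individual vector)`.
#' @return data.frame `individual_id`, `risk_lr`, `prodromal_lr`,
#'   `total_lr`.
#' @export
total_lr <- function(profiles, table, drop = character(0),
                     substitute_lr = NULL) {
  unknown <- setdiff(drop, table$markers$name)
  if (length(unknown)) stop("unknown marker(s) in drop: ",
                            paste(unknown, collapse = ", "))
  n <- nrow(profiles)
  out <- data.frame(individual_id = profiles$individual_id,
                    risk_lr = rep(1, n), prodromal_lr = rep(1, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(table$markers))) {
    mk <- table$markers$name[i]
    cls <- table$markers$class[i]
    if (!mk %in% names(profiles)) next  # marker not collected: contributes 1
    if (mk %in% drop) next
    if (!is.null(substitute_lr) && identical(substitute_lr$marker, mk)) {
      lr <- substitute_lr$lr
      if (length(lr) != n) stop("substitute LR length mismatch")
    } else {
      lr <- marker_lr(profiles[[mk]], mk, table)
    }
    col <- if (cls == "risk") "risk_lr" else "prodromal_lr"
    out[[col]] <- out[[col]] * lr
  }
  out$total_lr <- out$risk_lr * out$prodromal_lr
  out
}

#' Posttest probability from pretest probability and total LR
#'
#' Bayes' rule on the odds scale:
#' `post_odds = pretest/(1-pretest) * total_lr`, returned as
#' `post_odds / (1 + post_odds)`.
#'
#' @param pretest pretest probabilities strictly inside (0, 1).
#' @param lr positive total likelihood ratios.
#' @return posttest probabilities.
#' @export
posttest_probability <- function(pretest, lr) {
  if (any(pretest <= 0 | pretest >= 1))
    stop("pretest probability must be strictly between 0 and 1")
  if (any(lr <= 0)) stop("likelihood ratio must be positive")
  nmax <- max(length(pretest), length(lr))
  pretest <- rep_len(pretest, nmax)
  lr <- rep_len(lr, nmax)
  odds <- pretest / (1 - pretest) * lr
  post <- odds / (1 + odds)
  # a neutral total LR must return the pretest bit-for-bit (the all-missing
  # profile contract), which the odds round-trip does not guarantee
  post[lr == 1] <- pretest[lr == 1]
  post
}

#' Classify a posttest probability against the 30/50/80% cut-offs
#'
#' Flags are inclusive (a probability of exactly 0.30 counts as possible /
#' probable prodromal PD) and nested by construction.
#'
#' @param posttest probabilities in `[0, 1]`.
#' @return data.frame with logical columns `ge30`, `ge50`, `ge80`.
#' @export
classify_ppd <- function(posttest) {
  if (any(posttest < 0 | posttest > 1)) stop("probability out of [0, 1]")
  data.frame(ge30 = posttest >= 0.30, ge50 = posttest >= 0.50,
             ge80 = posttest >= 0.80)
}

#' Probability of prodromal PD for a cohort of marker profiles
#'
#' Individuals with a PD or dementia-with-Lewy-bodies diagnosis
#' (`pd_dlb_flag`) are removed before calculation (their count is recorded
#' in the `n_excluded_pd_dlb` attribute). For the rest: age-band pretest
#' probability, marker likelihood ratios (missing markers contribute 1.0),
#' class-wise LR products, and the posttest probability with the
#' 30/50/80% flags.
#'
#' @param profiles marker-profile data.frame with `individual_id`, `age`
#'   and marker state columns; optionally `pd_dlb_flag`.
#' @param table an [load_lr_table()] object.
#' @param drop marker names whose LR is forced to 1.0 for everyone.
#' @param substitute_lr see [total_lr()].
#' @return data.frame of class `ppd_result`: `individual_id`, `pretest`,
#'   `risk_lr`, `prodromal_lr`, `total_lr`, `posttest`, `ge30`, `ge50`,
#'   `ge80`.
#' @export
compute_ppd <- function(profiles, table = load_lr_table(),
                        drop = character(0), substitute_lr = NULL) {
  n_pd <- 0L
  if (!is.null(profiles$pd_dlb_flag)) {
    n_pd <- sum(profiles$pd_dlb_flag)
    profiles <- profiles[!profiles$pd_dlb_flag, , drop = FALSE]
  }
  pre <- pretest_probability(profiles$age, table)
  lrs <- total_lr(profiles, table, drop = drop, substitute_lr = substitute_lr)
  post <- posttest_probability(pre, lrs$total_lr)
  out <- cbind(data.frame(individual_id = profiles$individual_id,
                          pretest = pre, stringsAsFactors = FALSE),
               lrs[, c("risk_lr", "prodromal_lr", "total_lr")],
               data.frame(posttest = post), classify_ppd(post))
  attr(out, "n_excluded_pd_dlb") <- n_pd
  attr(out, "lr_table_hash") <- table$hash
  class(out) <- c("ppd_result", class(out))
  out
}

#' Recompute pPD probabilities with a marker excluded
#'
#' The marker-exclusion sensitivity analysis: the named marker's LR is
#' forced to 1.0 for every individual and the pipeline rerun unchanged.
#'
#' @inheritParams compute_ppd
#' @param drop marker name(s) to exclude.
#' @export
recompute_excluding <- function(profiles, table = load_lr_table(), drop) {
  compute_ppd(profiles, table, drop = drop)
}

#' Use the PRS top quartile as a risk marker
#'
#' The sensitivity scheme replaces one configured marker (by default the
#' first-degree-relative marker) with a likelihood ratio read off the
#' individual's PRS quartile: top quartile 1.57, middle two quartiles 1.00,
#' bottom quartile 0.45.
#'
#' @inheritParams compute_ppd
#' @param quartiles factor/character of Q1-Q4 labels, one per profile row
#'   (same order), or named by individual id.
#' @param replace the marker being substituted.
#' @param scheme named LR vector for Q1..Q4; defaults to the table's
#'   `prs_quartile_scheme`.
#' @export
substitute_prs_marker <- function(profiles, table = load_lr_table(),
                                  quartiles,
                                  replace = "first_degree_relative_pd",
                                  scheme = NULL) {
  scheme <- scheme %||% table$prs_quartile_scheme
  if (!replace %in% table$markers$name) stop("unknown marker: ", replace)
  if (!is.null(profiles$pd_dlb_flag) && is.null(names(quartiles))) {
    # keep the per-row quartile vector aligned with the PD/DLB pre-filter
    quartiles <- quartiles[!profiles$pd_dlb_flag]
    profiles <- profiles[!profiles$pd_dlb_flag, , drop = FALSE]
  }
  q <- quartiles
  if (!is.null(names(q))) q <- q[as.character(profiles$individual_id)]
  q <- as.character(q)
  if (length(q) != nrow(profiles) || anyNA(q))
    stop("missing PRS quartile for one or more individuals")
  lr <- unname(scheme[q])
  if (anyNA(lr)) stop("quartile labels must be Q1..Q4")
  compute_ppd(profiles, table,
              substitute_lr = list(marker = replace, lr = lr))
}
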