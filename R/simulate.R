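#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: an elderly
#' population cohort (all ages >= 65, majority female), biallelic SNPs in
#' Hardy-Weinberg equilibrium with block LD, a discovery GWAS whose
#' genome-wide-significant tier holds on the order of ninety SNPs, marker
#' prevalences that place roughly 5% of individuals at >= 30% prodromal-PD
#' probability, and a latent genetic liability that loads negatively on
#' cognition. Defaults encode those conditions; override any field by name.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of biallelic SNPs.
#' @param maf_range range the per-variant minor allele frequency is drawn
#'   from, in (0, 0.5].
#' @param ld_block_size variants per LD block (last block may be shorter).
#' @param ld_rho within-block AR(1) haplotype correlation in `[0, 1)`.
#' @param n_causal number of causal variants (true nonzero effects);
#'   `NULL` (the default) uses 8% of `n_variants`, the causal density that
#'   yields a genome-wide-significant tier of ~90 SNPs at the default
#'   panel size.
#' @param effect_sd standard deviation of true per-allele effects.
#' @param n_discovery discovery GWAS sample size used to generate standard
#'   errors and p-values.
#' @param age_range ages drawn uniformly over this interval (min >= 65 by
#'   default; band membership for the age priors is all that matters).
#' @param prop_female fraction of females.
#' @param marker_prevalences named vector of baseline marker prevalences
#'   (the cognitive-deficit marker is instead derived from the liability).
#' @param liability_loading coupling of the standardized true genetic score
#'   to the cognitive-domain z-scores (0 = no coupling).
#' @param cognitive_deficit_threshold composite-z cut-off below which the
#'   global cognitive deficit marker is present. The criteria literature does
#'   not fix this operationalization, so it is an explicit knob.
#' @param missing_rate independent missingness rate applied per genotype
#'   call and per marker state.
#' @param seed integer seed; identical configs give bit-identical cohorts.
#'
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 1120,
                              n_variants = 2000,
                              maf_range = c(0.05, 0.5),
                              ld_block_size = 10,
                              ld_rho = 0.8,
                              n_causal = NULL,
                              effect_sd = 0.05,
                              n_discovery = 1e5,
                              age_range = c(65, 90),
                              prop_female = 0.576,
                              marker_prevalences = default_marker_prevalences(),
                              liability_loading = 0.5,
                              cognitive_deficit_threshold = -0.6,
                              missing_rate = 0.02,
                              seed = 1L) {
  if (is.null(n_causal)) n_causal <- max(1, round(0.08 * n_variants))
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              ld_block_size = as.integer(ld_block_size),
              ld_rho = as.numeric(ld_rho),
              n_causal = as.integer(n_causal),
              effect_sd = as.numeric(effect_sd),
              n_discovery = as.numeric(n_discovery),
              age_range = as.numeric(age_range),
              prop_female = as.numeric(prop_female),
              marker_prevalences = marker_prevalences,
              liability_loading = as.numeric(liability_loading),
              cognitive_deficit_threshold = as.numeric(cognitive_deficit_threshold),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Default baseline marker prevalences
#'
#' Chosen once so that the default cohort lands near the target composition:
#' about 5% of individuals at >= 30% posttest probability, a few percent with
#' a first-degree relative with PD, and realistic elderly-population rates
#' for the lifestyle and autonomic markers.
#' @export
default_marker_prevalences <- function() {
  c(pesticide_exposure = 0.20,
    non_use_of_caffeine = 0.30,
    non_smoking = 0.60,
    first_degree_relative_pd = 0.04,
    dm2 = 0.15,
    physical_inactivity = 0.30,
    possible_rbd = 0.08,
    subthreshold_parkinsonism = 0.12,
    constipation = 0.17,
    excessive_daytime_somnolence = 0.10,
    symptomatic_orthostatic_hypotension = 0.08,
    erectile_dysfunction = 0.20,
    urinary_dysfunction = 0.25,
    depression_anxiety = 0.25)
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 1, cfg$n_variants >= 1)
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie in (0, 0.5] with min <= max")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (cfg$ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (cfg$n_causal > cfg$n_variants) stop("n_causal cannot exceed n_variants")
  if (cfg$n_discovery <= 0) stop("n_discovery must be positive")
  for (f in c("prop_female", "missing_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (any(cfg$marker_prevalences < 0 | cfg$marker_prevalences > 1))
    stop("marker prevalences must be in [0, 1]")
  if (cfg$age_range[1] > cfg$age_range[2]) stop("malformed age_range")
  invisible(cfg)
}

# chromosome / position layout: each LD block occupies its own 2 Mb slot and
# blocks cycle over chromosomes 1..22, so clumping windows (+-250 kb) never
# span blocks and chromosome 6 acquires blocks inside the 27-33 Mb MHC slice.
variant_layout <- function(n_variants, block_size) {
  j <- seq_len(n_variants)
  block <- (j - 1L) %/% block_size
  within <- (j - 1L) %% block_size
  chrom <- (block %% 22L) + 1L
  slot <- block %/% 22L
  pos <- 25e6 + slot * 2e6 + within * 1e4
  data.frame(block = block + 1L, chrom = chrom, pos = as.numeric(pos))
}

#' Simulate a genotype matrix with block LD
#'
#' Haplotypes are drawn from a Gaussian copula: standard-normal AR(1) series
#' within each LD block (correlation `ld_rho` between adjacent variants),
#' thresholded at the normal quantile of each variant's allele frequency.
#' Summing two independent haplotypes yields dosages that satisfy
#' Hardy-Weinberg equilibrium at each variant while carrying tunable
#' within-block LD; between-block correlation is zero by construction.
#'
#' @param config a [simulation_config()].
#' @return a [genotype_matrix()]; the drawn (true) allele frequencies are
#'   attached as attribute `drawn_maf`.
#' @export
simulate_genotypes <- function(config) {
  validate_simulation_config(config)
  n <- config$n_individuals; m <- config$n_variants
  withr::with_seed(config$seed + 1L, {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    lay <- variant_layout(m, config$ld_block_size)
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    hap <- function() {
      z <- matrix(rnorm(n * m), n, m)
      rho <- config$ld_rho
      if (rho > 0 && m > 1) {
        for (j in 2:m) {
          if (lay$block[j] == lay$block[j - 1L])
            z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
        }
      }
      z
    }
    thr <- qnorm(maf)
    d <- (sweep(hap(), 2, thr, "<") + 0) + (sweep(hap(), 2, thr, "<") + 0)
    if (config$missing_rate > 0) {
      miss <- matrix(runif(n * m) < config$missing_rate, n, m)
      d[miss] <- NA_real_
    }
    info <- round(1 - rbeta(m, 1, 12), 4)
    variants <- data.frame(
      variant_id = sprintf("var%05d", seq_len(m)),
      chrom = lay$chrom, pos = lay$pos, ref = ref, alt = alt,
      info_score = info, stringsAsFactors = FALSE)
    ids <- sprintf("ind%04d", seq_len(n))
    gm <- genotype_matrix(d, variants, ids)
    attr(gm, "drawn_maf") <- maf
    gm
  })
}

#' Simulate discovery GWAS summary statistics
#'
#' A random set of `n_causal` variants receives true per-allele effects
#' drawn N(0, `effect_sd`); all other true effects are zero. Each reported
#' effect is the true effect plus estimation noise with standard error
#' `1/sqrt(2 * n_discovery * maf * (1 - maf))`, and the two-sided p-value
#' comes from the Wald statistic. The effect allele is the ALT allele of the
#' target matrix.
#'
#' @param config a [simulation_config()].
#' @param genotypes the [genotype_matrix()] the cohort was generated with.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `maf`;
#'   attributes `true_beta` (length `n_variants`) and `causal_idx`.
#' @export
simulate_summary_stats <- function(config, genotypes) {
  validate_simulation_config(config)
  if (config$n_discovery <= 0) stop("n_discovery must be positive")
  v <- genotypes$variants
  m <- nrow(v)
  maf <- attr(genotypes, "drawn_maf") %||% pmax(v$maf, 1e-3)
  withr::with_seed(config$seed + 2L, {
    causal <- sort(sample.int(m, config$n_causal))
    true_beta <- numeric(m)
    true_beta[causal] <- rnorm(config$n_causal, 0, config$effect_sd)
    se <- 1 / sqrt(2 * config$n_discovery * maf * (1 - maf))
    beta_hat <- true_beta + rnorm(m, 0, se)
    p <- 2 * pnorm(-abs(beta_hat / se))
    p <- pmax(p, .Machine$double.xmin)
    ss <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                     effect_allele = v$alt, other_allele = v$ref,
                     beta = beta_hat, se = se, pvalue = p, maf = maf,
                     stringsAsFactors = FALSE)
    attr(ss, "true_beta") <- true_beta
    attr(ss, "causal_idx") <- causal
    ss
  })
}

#' Simulate marker profiles tied to a genetic liability
#'
#' Emits the seven risk markers (sex, pesticide exposure, non-use of
#' caffeine, non-smoking, first-degree relative with PD, type-2 diabetes,
#' physical inactivity) and nine prodromal markers (possible RBD,
#' subthreshold parkinsonism, constipation, excessive daytime somnolence,
#' symptomatic orthostatic hypotension, erectile dysfunction, urinary
#' dysfunction, depression/anxiety, global cognitive deficit) as
#' present/absent/missing states, plus five cognitive-domain z-scores with
#' negative loading on the standardized true genetic score. The global
#' cognitive deficit marker and the dementia / MCI flags are thresholds on
#' the composite z-score. Erectile dysfunction is always missing for
#' females; every other marker goes missing independently at `missing_rate`.
#'
#' @param config a [simulation_config()].
#' @param true_scores per-individual genetic liability (finite numeric).
#' @param individual_ids ids matching `true_scores`.
#' @return data.frame of marker profiles, one row per individual.
#' @export
simulate_markers <- function(config, true_scores, individual_ids) {
  validate_simulation_config(config)
  if (length(true_scores) != length(individual_ids))
    stop("true_scores and individual_ids length mismatch")
  if (any(!is.finite(true_scores))) stop("true_scores must be finite")
  n <- length(true_scores)
  withr::with_seed(config$seed + 3L, {
    age <- runif(n, config$age_range[1], config$age_range[2])
    female <- runif(n) < config$prop_female
    s <- if (sd(true_scores) > 0) as.numeric(scale(true_scores)) else numeric(n)
    domains <- cognitive_domains()
    w <- c(memory = 0.8, language = 0.7, attention_speed = 1.0,
           executive = 0.8, visual_spatial = 0.6)
    z <- sapply(domains, function(d)
      -config$liability_loading * w[[d]] * s + rnorm(n))
    colnames(z) <- paste0("z_", domains)
    composite <- rowMeans(z)
    deficit <- composite <= config$cognitive_deficit_threshold
    dementia <- composite <= -1.2
    mci <- !dementia & composite <= -0.7

    prev <- config$marker_prevalences
    state <- function(present) ifelse(present, "present", "absent")
    prof <- data.frame(individual_id = individual_ids,
                       age = age,
                       sex = ifelse(female, "female", "male"),
                       stringsAsFactors = FALSE)
    prof$male_sex <- state(!female)
    for (mk in names(prev))
      prof[[mk]] <- state(runif(n) < prev[[mk]])
    prof$global_cognitive_deficit <- state(deficit)
    # independent missingness per marker/individual (sex itself is never
    # missing, so male_sex stays observed)
    maskable <- c(names(prev), "global_cognitive_deficit")
    for (mk in maskable)
      prof[[mk]][runif(n) < config$missing_rate] <- "missing"
    prof$erectile_dysfunction[female] <- "missing"
    prof <- cbind(prof, as.data.frame(z))
    prof$dementia_flag <- dementia
    prof$mci_flag <- mci
    prof$pd_dlb_flag <- FALSE
    prof
  })
}

#' Names of the cognitive domains carried as z-scores
#' @export
cognitive_domains <- function() {
  c("memory", "language", "attention_speed", "executive", "visual_spatial")
}

#' Generate a complete synthetic cohort
#'
#' Runs [simulate_genotypes()], [simulate_summary_stats()] and
#' [simulate_markers()] under one seed and couples them through the true
#' genetic score (mean-imputed dosages weighted by the true causal effects),
#' which is the oracle liability the markers load on.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort` with elements `genotypes`,
#'   `sumstats`, `profiles`, `true_scores`, `truth_log`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  gm <- simulate_genotypes(config)
  ss <- simulate_summary_stats(config, gm)
  true_beta <- attr(ss, "true_beta")
  true_scores <- as.numeric(imputed_dosages(gm) %*% true_beta)
  names(true_scores) <- gm$individual_ids
  prof <- simulate_markers(config, true_scores, gm$individual_ids)
  structure(list(genotypes = gm, sumstats = ss, profiles = prof,
                 true_scores = true_scores, truth_log = list(),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d individuals, %d variants, %d injected failure kinds\n",
    length(x$genotypes$individual_ids), nrow(x$genotypes$variants),
    length(x$truth_log)))
  invisible(x)
}

#' Inject known quality-control failures into a synthetic cohort
#'
#' Adds samples or variants that violate one QC rule each, with a margin
#' wide enough that the corresponding filter must catch them, and records
#' the injections in `truth_log` so detection can be scored. Entries not
#' named by an injection are left bit-identical.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param spec named list mapping a failure kind to how many to inject.
#'   Kinds: `high_missingness_sample`, `extreme_heterozygosity`,
#'   `duplicate_sample`, `relative_pair`, `ancestry_outlier`,
#'   `high_missingness_variant`, `hwe_violation`, `duplicate_variant`,
#'   `ambiguous_variant`.
#' @return the cohort with failures applied and `truth_log` updated.
#' @export
inject_qc_failures <- function(cohort, spec) {
  if (!inherits(cohort, "synthetic_cohort")) stop("not a synthetic_cohort")
  if (length(spec) == 0) return(cohort)
  known <- c("high_missingness_sample", "extreme_heterozygosity",
             "duplicate_sample", "relative_pair", "ancestry_outlier",
             "high_missingness_variant", "hwe_violation",
             "duplicate_variant", "ambiguous_variant")
  bad <- setdiff(names(spec), known)
  if (length(bad)) stop("unknown failure kind(s): ", paste(bad, collapse = ", "))

  gm <- cohort$genotypes
  d <- gm$dosages
  v <- gm$variants
  ids <- gm$individual_ids
  info <- v$info_score
  log <- cohort$truth_log
  profiles <- cohort$profiles
  true_scores <- cohort$true_scores

  withr::with_seed(cohort$config$seed + 4L, {
    n <- nrow(d); m <- ncol(d)
    free_samples <- sample(seq_len(n))   # disjoint pool of targets
    free_variants <- sample(seq_len(m))
    take_s <- function(k) { out <- free_samples[seq_len(k)]
      free_samples <<- free_samples[-seq_len(k)]; out }
    take_v <- function(k) { out <- free_variants[seq_len(k)]
      free_variants <<- free_variants[-seq_len(k)]; out }

    for (kind in names(spec)) {
      k <- spec[[kind]]
      if (kind == "high_missingness_sample") {
        rows <- take_s(k)
        for (r in rows) d[r, sample.int(m, ceiling(0.10 * m))] <- NA_real_
        log$high_missingness_sample <- c(log$high_missingness_sample, ids[rows])
      } else if (kind == "extreme_heterozygosity") {
        rows <- take_s(k)
        for (r in rows) d[r, !is.na(d[r, ])] <- 1
        log$extreme_heterozygosity <- c(log$extreme_heterozygosity, ids[rows])
      } else if (kind == "duplicate_sample") {
        rows <- take_s(k)
        for (r in rows) {
          new <- d[r, ]
          obs <- which(!is.na(new))
          flip <- sample(obs, max(1L, round(0.01 * length(obs))))
          new[flip] <- (new[flip] + sample(1:2, length(flip), TRUE)) %% 3
          d <- rbind(d, new)
          new_id <- paste0(ids[r], "_dup")
          ids <- c(ids, new_id)
          pr <- profiles[profiles$individual_id == ids[r], , drop = FALSE]
          pr$individual_id <- new_id
          profiles <- rbind(profiles, pr)
          true_scores <- c(true_scores, setNames(true_scores[r], new_id))
          log$duplicate_sample <- c(log$duplicate_sample,
                                    list(c(ids[r], new_id)))
        }
      } else if (kind == "relative_pair") {
        rows <- take_s(k)
        p_alt <- colMeans(d, na.rm = TRUE) / 2
        for (r in rows) {
          par <- d[r, ]
          par_obs <- ifelse(is.na(par), round(2 * p_alt), par)
          transmitted <- rbinom(m, 1, par_obs / 2)
          other <- rbinom(m, 1, p_alt)
          d <- rbind(d, transmitted + other)
          new_id <- paste0(ids[r], "_rel")
          ids <- c(ids, new_id)
          pr <- profiles[profiles$individual_id == ids[r], , drop = FALSE]
          pr$individual_id <- new_id
          profiles <- rbind(profiles, pr)
          true_scores <- c(true_scores, setNames(true_scores[r], new_id))
          log$relative_pair <- c(log$relative_pair, list(c(ids[r], new_id)))
        }
      } else if (kind == "ancestry_outlier") {
        rows <- take_s(k)
        p_alt <- colMeans(d, na.rm = TRUE) / 2
        for (r in rows) d[r, ] <- rbinom(m, 2, pmin(0.95, p_alt + 0.3))
        log$ancestry_outlier <- c(log$ancestry_outlier, ids[rows])
      } else if (kind == "high_missingness_variant") {
        cols <- take_v(k)
        for (cc in cols) d[sample.int(nrow(d), ceiling(0.10 * nrow(d))), cc] <- NA_real_
        log$high_missingness_variant <- c(log$high_missingness_variant,
                                          v$variant_id[cols])
      } else if (kind == "hwe_violation") {
        cols <- take_v(k)
        for (cc in cols) d[, cc] <- 1
        log$hwe_violation <- c(log$hwe_violation, v$variant_id[cols])
      } else if (kind == "duplicate_variant") {
        cols <- take_v(k)
        for (cc in cols) {
          new <- d[, cc]
          # slightly higher missingness than the original, but safely below
          # the 0.05 variant-missingness bound so only the dedup rule fires
          new[sample.int(nrow(d), ceiling(0.02 * nrow(d)))] <- NA_real_
          d <- cbind(d, new)
          nv <- v[cc, , drop = FALSE]
          nv$variant_id <- paste0(v$variant_id[cc], "_dup")
          v <- rbind(v, nv)
          info <- c(info, info[cc])
          log$duplicate_variant <- c(log$duplicate_variant,
                                     list(c(v$variant_id[cc], nv$variant_id)))
        }
      } else if (kind == "ambiguous_variant") {
        cols <- take_v(k)
        for (cc in cols) {
          v$ref[cc] <- "A"; v$alt[cc] <- "T"
          d[, cc] <- rbinom(nrow(d), 2, 0.45)
        }
        log$ambiguous_variant <- c(log$ambiguous_variant, v$variant_id[cols])
      }
    }
  })

  gm2 <- genotype_matrix(d, v[, c("variant_id", "chrom", "pos", "ref", "alt")],
                         ids, genome_build = gm$genome_build)
  gm2$variants$info_score <- info
  attr(gm2, "drawn_maf") <- NULL
  cohort$genotypes <- gm2
  cohort$profiles <- profiles
  cohort$true_scores <- true_scores
  cohort$truth_log <- log
  cohort
}
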