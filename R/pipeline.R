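#' Pipeline run configuration
#'
#' Exactly one of `simulation` (a [simulation_config()]) or `inputs` (a
#' list with paths `genotypes`, `genotype_format`, `sumstats`, `profiles`)
#' must be supplied.
#'
#' @param outdir output directory (created if needed).
#' @param simulation optional [simulation_config()].
#' @param inputs optional list of input paths.
#' @param thresholds PRS p-value thresholds.
#' @param qc a [qc_thresholds()].
#' @param clump a [clump_params()].
#' @param lr_table_path YAML LR table; default the shipped table.
#' @param covariate_sets covariate sets for the model battery.
#' @param include_joint append joint cognitive models to the battery.
#' @param sensitivity run the sensitivity battery variants (dementia / MCI
#'   exclusions, marker exclusion, family-history subgroups, PRS-quartile
#'   marker substitution).
#' @param seed integer seed for any simulation randomness.
#' @param write_vcf also write the simulated genotypes as a VCF.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, simulation = NULL, inputs = NULL,
                       thresholds = default_thresholds(),
                       qc = qc_thresholds(), clump = clump_params(),
                       lr_table_path = NULL,
                       covariate_sets = c("standard", "fully_adjusted"),
                       include_joint = FALSE, sensitivity = FALSE,
                       seed = 1L, write_vcf = FALSE) {
  if (is.null(simulation) == is.null(inputs))
    stop("exactly one of 'simulation' or 'inputs' must be given")
  structure(list(outdir = outdir, simulation = simulation, inputs = inputs,
                 thresholds = thresholds, qc = qc, clump = clump,
                 lr_table_path = lr_table_path,
                 covariate_sets = covariate_sets,
                 include_joint = include_joint, sensitivity = sensitivity,
                 seed = as.integer(seed), write_vcf = write_vcf),
            class = "run_config")
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

config_hash <- function(config) {
  clean <- config[setdiff(names(config), "outdir")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(clean, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline: cohort, QC, PRS, pPD, associations
#'
#' Executes the stages in order, writes per-stage TSV/JSON artifacts into
#' `config$outdir`, and returns a manifest. Reruns with an identical
#' configuration reproduce byte-identical primary result tables.
#'
#' Artifacts: `genotypes.tsv` (and optionally `genotypes.vcf`),
#' `sumstats.tsv`, `profiles.tsv`, `truth_log.json`, `qc_report.json`,
#' `pcs.tsv`, `prs_profiles.tsv`, `ppd_results.tsv`, `associations.tsv`
#' (plus `associations_sensitivity.tsv`), `manifest.json`, `run.log`.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (list with config hash, LR-table hash,
#'   seed, per-stage row counts and package version).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$outdir, "run.log"), open = "wt")
  on.exit(close(logf))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  lr_table <- if (is.null(config$lr_table_path)) load_lr_table()
              else load_lr_table(config$lr_table_path)

  # stage 1: cohort --------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- config$seed
    cohort <- stage("simulate", simulate_cohort(sim_cfg))
    gm <- cohort$genotypes
    sumstats <- cohort$sumstats
    profiles <- cohort$profiles
    pipeline_log(logf, "simulate: %d individuals, %d variants",
                 length(gm$individual_ids), nrow(gm$variants))
    write_dosage_tsv(gm, file.path(config$outdir, "genotypes.tsv"))
    if (isTRUE(config$write_vcf))
      write_vcf(gm, file.path(config$outdir, "genotypes.vcf"))
    write_sumstats_tsv(sumstats, file.path(config$outdir, "sumstats.tsv"))
    write_profiles_tsv(profiles, file.path(config$outdir, "profiles.tsv"))
    write_truth_log_json(cohort$truth_log,
                         file.path(config$outdir, "truth_log.json"))
  } else {
    gm <- stage("read_genotypes",
                read_genotypes(config$inputs$genotypes,
                               config$inputs$genotype_format %||% "dosage_tsv"))
    sumstats <- stage("read_sumstats",
                      read_sumstats_tsv(config$inputs$sumstats))
    profiles <- stage("read_profiles",
                      read_profiles_tsv(config$inputs$profiles))
    pipeline_log(logf, "load: %d individuals, %d variants",
                 length(gm$individual_ids), nrow(gm$variants))
  }

  # stage 2: genotype QC ----------------------------------------------------
  qc <- stage("genotype_qc", run_genotype_qc(gm, config$qc))
  pipeline_log(logf, "qc: kept %d/%d samples, %d/%d variants",
               qc$summary_counts[["kept_samples"]],
               qc$summary_counts[["input_samples"]],
               qc$summary_counts[["kept_variants"]],
               qc$summary_counts[["input_variants"]])
  jsonlite::write_json(
    list(excluded_samples = as.list(qc$excluded_samples),
         excluded_variants = as.list(qc$excluded_variants),
         summary_counts = as.list(qc$summary_counts),
         kinship_cutoff_used = qc$kinship_cutoff_used,
         kinship_fallback = qc$kinship_fallback,
         skipped_checks = qc$skipped_checks),
    file.path(config$outdir, "qc_report.json"), auto_unbox = TRUE,
    pretty = TRUE)
  pcs_dt <- data.frame(individual_id = rownames(qc$pcs), qc$pcs,
                       row.names = NULL)
  data.table::fwrite(pcs_dt, file.path(config$outdir, "pcs.tsv"), sep = "\t")

  # stage 3: PRS ------------------------------------------------------------
  prs <- stage("prs", build_prs_profiles(qc$kept_matrix, sumstats,
                                         thresholds = config$thresholds,
                                         params = config$clump))
  pipeline_log(logf, "prs: %d index SNPs after clumping",
               nrow(attr(prs, "clumped")))
  data.table::fwrite(prs, file.path(config$outdir, "prs_profiles.tsv"),
                     sep = "\t")

  # stage 4: pPD probability -----------------------------------------------
  kept_profiles <- profiles[profiles$individual_id %in%
                              qc$kept_matrix$individual_ids, , drop = FALSE]
  ppd <- stage("ppd", compute_ppd(kept_profiles, lr_table))
  pipeline_log(logf, "ppd: %d individuals, %.1f%% at >=30%%",
               nrow(ppd), 100 * mean(ppd$ge30))
  data.table::fwrite(ppd, file.path(config$outdir, "ppd_results.tsv"),
                     sep = "\t")

  # stage 5: association battery --------------------------------------------
  battery <- stage("associate",
                   run_model_battery(prs, ppd, kept_profiles, qc$pcs,
                                     table = lr_table,
                                     covariate_sets = config$covariate_sets,
                                     include_joint = config$include_joint))
  data.table::fwrite(battery, file.path(config$outdir, "associations.tsv"),
                     sep = "\t")
  pipeline_log(logf, "associate: %d model rows", nrow(battery))

  # stage 6: sensitivity variants -------------------------------------------
  n_sens <- 0L
  if (isTRUE(config$sensitivity)) {
    sens <- stage("sensitivity",
                  run_sensitivity_battery(prs, kept_profiles, qc$pcs, lr_table,
                                          covariate_sets = config$covariate_sets))
    data.table::fwrite(sens, file.path(config$outdir,
                                       "associations_sensitivity.tsv"),
                       sep = "\t")
    n_sens <- nrow(sens)
    pipeline_log(logf, "sensitivity: %d model rows", n_sens)
  }

  manifest <- list(
    package_version = as.character(packageVersion("prodromalPRS")),
    seed = config$seed,
    config_hash = config_hash(config),
    lr_table_hash = lr_table$hash,
    stages = list(
      cohort = list(individuals = length(gm$individual_ids),
                    variants = nrow(gm$variants)),
      qc = as.list(qc$summary_counts),
      prs = list(index_snps = nrow(attr(prs, "clumped")),
                 thresholds = length(config$thresholds)),
      ppd = list(individuals = nrow(ppd),
                 pct_ge30 = 100 * mean(ppd$ge30)),
      associate = list(rows = nrow(battery)),
      sensitivity = list(rows = n_sens)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log(logf, "done in %.1fs",
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}

#' Sensitivity-analysis model battery
#'
#' Reruns the primary battery under the sensitivity designs: excluding
#' dementia, excluding dementia and MCI, excluding the global cognitive
#' deficit marker (pPD recomputed), excluding the first-degree-relative
#' marker, the family-history subgroups, and the PRS-top-quartile-as-risk-
#' marker substitution. Returns one stacked table with a `variant` column.
#'
#' @param prs a [build_prs_profiles()] result.
#' @param profiles marker profiles of the analysis cohort.
#' @param pcs principal components.
#' @param table an [load_lr_table()] object.
#' @param covariate_sets covariate sets, as in [run_model_battery()].
#' @param prs_marker_threshold the threshold whose quartiles feed the
#'   PRS-as-marker substitution.
#' @export
run_sensitivity_battery <- function(prs, profiles, pcs,
                                    table = load_lr_table(),
                                    covariate_sets = "standard",
                                    prs_marker_threshold = 5e-8) {
  ppd0 <- compute_ppd(profiles, table)
  pieces <- list()
  add <- function(label, battery) {
    battery$variant <- label
    pieces[[length(pieces) + 1L]] <<- battery
  }
  add("no_dementia", run_model_battery(prs, ppd0, profiles, pcs, table,
                                       covariate_sets, subset = "no_dementia"))
  add("no_dementia_mci",
      run_model_battery(prs, ppd0, profiles, pcs, table,
                        covariate_sets, subset = "no_dementia_mci"))
  ppd_nocog <- recompute_excluding(profiles, table,
                                   drop = "global_cognitive_deficit")
  add("drop_cognitive_deficit",
      run_model_battery(prs, ppd_nocog, profiles, pcs, table,
                        covariate_sets))
  ppd_nofdr <- recompute_excluding(profiles, table,
                                   drop = "first_degree_relative_pd")
  add("drop_first_degree_relative",
      run_model_battery(prs, ppd_nofdr, profiles, pcs, table,
                        covariate_sets))
  add("fdr_present", run_model_battery(prs, ppd0, profiles, pcs, table,
                                       covariate_sets, subset = "fdr_present"))
  add("fdr_absent", run_model_battery(prs, ppd0, profiles, pcs, table,
                                      covariate_sets, subset = "fdr_absent"))
  sc <- prs[abs(prs$threshold - prs_marker_threshold) < 1e-15, ]
  q <- setNames(as.character(sc$quartile), sc$individual_id)
  ppd_q <- substitute_prs_marker(profiles, table, quartiles = q)
  add("prs_quartile_marker",
      run_model_battery(prs, ppd_q, profiles, pcs, table, covariate_sets))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
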