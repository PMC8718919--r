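#' Pipeline configuration
#'
#' Settings for the end-to-end run: cohort generation, screening, feature
#' extraction, model fitting, Z-scoring and validation. A single seed
#' governs all stochastic stages through fixed per-stage substreams, so
#' each stage is individually reproducible and a rerun with the same
#' configuration yields byte-identical artifacts.
#'
#' @param out_dir directory that receives all artifacts.
#' @param cohort a [cohort_config()] for the training cohort (its seed is
#'   overridden by the derived substream of \code{seed}).
#' @param holdout_n_per_sex held-out normative subjects per sex for
#'   validation (default 100).
#' @param sex_modes models to fit (default male, female and pooled).
#' @param half_width age-band baseline window half-width in years.
#' @param n_interior,lambda_grid spline fitting parameters.
#' @param threshold,gate_alpha validation map thresholds.
#' @param eeg_dir optional directory of raw EEG CSV files (header =
#'   channel labels); when given, the extract stage computes band powers
#'   from these instead of passing through the simulated features.
#' @param fs sampling rate of the raw CSVs in Hz.
#' @param seed master integer seed.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(),
                            holdout_n_per_sex = 100,
                            sex_modes = c("male", "female", "pooled"),
                            half_width = 5,
                            n_interior = 10,
                            lambda_grid = default_lambda_grid(),
                            threshold = 0.1, gate_alpha = 0.05,
                            eeg_dir = NULL, fs = 250,
                            seed = 1L) {
  structure(list(out_dir = out_dir, cohort = cohort,
                 holdout_n_per_sex = holdout_n_per_sex,
                 sex_modes = sex_modes, half_width = half_width,
                 n_interior = n_interior, lambda_grid = lambda_grid,
                 threshold = threshold, gate_alpha = gate_alpha,
                 eeg_dir = eeg_dir, fs = fs, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_file <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(config, name, produced_by) {
  p <- stage_file(config, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "'; run the '", produced_by,
         "' stage first")
  p
}

# Derived per-stage substreams of the master seed (kept below 2^31).
stage_seed <- function(config, offset) (config$seed * 131L + offset) %% 2000000000L

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the normative-database pipeline
#'
#' Executes the requested stages in order: \code{simulate} (draw the
#' synthetic cohort), \code{screen} (apply the four normative criteria),
#' \code{extract} (band-power feature table, from raw CSV EEG if
#' configured, otherwise the simulated features), \code{fit} (spline
#' normative models per configured sex mode, plus the age-band baseline),
#' \code{zscore} (standardize every subject against the model matching
#' their sex) and \code{validate} (calibration, cross-model correlation,
#' sex-difference map and the stratified-versus-pooled anomaly contrast).
#' Every artifact embeds the configuration echo; no timestamps are
#' written, so identical configurations reproduce identical files.
#'
#' @param config a [pipeline_config()].
#' @param stages ordered subset of
#'   \code{c("simulate","screen","extract","fit","zscore","validate")};
#'   default all.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "screen", "extract",
                                    "fit", "zscore", "validate")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()

  cfg_echo <- config
  cfg_echo$out_dir <- NULL   # paths excluded so the echo is run-invariant
  cfg_echo$eeg_dir <- NULL
  cfg_echo$cohort <- unclass(cfg_echo$cohort)
  jsonlite::write_json(unclass(cfg_echo), stage_file(config, "config.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)

  if ("simulate" %in% stages) {
    cc <- config$cohort
    cc$seed <- stage_seed(config, 1L)
    cohort <- sample_cohort(cc)
    artifacts$demographics <- write_table(
      cohort$demographics, stage_file(config, "cohort_demographics.csv"))
    artifacts$screening <- write_table(
      cohort$screening, stage_file(config, "cohort_screening.csv"))
    artifacts$powers <- write_table(
      cohort$powers, stage_file(config, "cohort_powers.csv"))
  }

  if ("screen" %in% stages) {
    demo <- utils::read.csv(require_artifact(config,
                                             "cohort_demographics.csv",
                                             "simulate"))
    scr <- utils::read.csv(require_artifact(config, "cohort_screening.csv",
                                            "simulate"))
    res <- screen_cohort(merge(demo[, c("id", "age", "sex")], scr,
                               by = "id", sort = FALSE))
    artifacts$screening_results <- write_table(
      res, stage_file(config, "screening_results.csv"))
  }

  if ("extract" %in% stages) {
    if (!is.null(config$eeg_dir)) {
      files <- list.files(config$eeg_dir, pattern = "\\.csv$",
                          full.names = TRUE)
      if (!length(files)) stop("eeg_dir contains no CSV recordings")
      recs <- lapply(files, function(f)
        preprocess(read_eeg_csv(f, fs = config$fs)))
      tab <- build_band_power_table(recs)
    } else {
      pw <- utils::read.csv(require_artifact(config, "cohort_powers.csv",
                                             "simulate"))
      tab <- pw[, c("id", "channel", "band", "power_uv2", "log_power")]
    }
    artifacts$band_power_table <- write_table(
      tab, stage_file(config, "band_power_table.csv"))
  }

  if ("fit" %in% stages) {
    tab <- utils::read.csv(require_artifact(config, "band_power_table.csv",
                                            "extract"))
    demo <- utils::read.csv(require_artifact(config,
                                             "cohort_demographics.csv",
                                             "simulate"))
    scr_res <- utils::read.csv(require_artifact(config,
                                                "screening_results.csv",
                                                "screen"))
    eligible <- scr_res$id[scr_res$eligible]
    for (sm in config$sex_modes) {
      mod <- fit_normative_model(powers = tab, demographics = demo,
                                 sex_mode = sm, eligible_ids = eligible,
                                 n_interior = config$n_interior,
                                 lambda_grid = config$lambda_grid)
      f <- stage_file(config, paste0("model_", sm, ".json"))
      save_model(mod, f)
      artifacts[[paste0("model_", sm)]] <- f
    }
    ab <- fit_age_band_model(powers = tab, demographics = demo,
                             sex_mode = "pooled", eligible_ids = eligible,
                             half_width = config$half_width)
    f <- stage_file(config, "model_age_band.json")
    save_model(ab, f)
    artifacts$model_age_band <- f
  }

  if ("zscore" %in% stages) {
    tab <- utils::read.csv(require_artifact(config, "band_power_table.csv",
                                            "extract"))
    demo <- utils::read.csv(require_artifact(config,
                                             "cohort_demographics.csv",
                                             "simulate"))
    zs <- list()
    for (sm in intersect(c("male", "female"), config$sex_modes)) {
      mod <- load_model(require_artifact(config,
                                         paste0("model_", sm, ".json"),
                                         "fit"))
      ids <- demo$id[demo$sex == sm]
      zs[[sm]] <- zscore(mod, tab[tab$id %in% ids, ], demo)
    }
    if (!length(zs)) {
      mod <- load_model(require_artifact(config, "model_pooled.json",
                                         "fit"))
      zs$pooled <- zscore(mod, tab, demo)
    }
    artifacts$zscores <- write_table(do.call(rbind, zs),
                                     stage_file(config, "zscores.csv"))
  }

  if ("validate" %in% stages) {
    demo <- utils::read.csv(require_artifact(config,
                                             "cohort_demographics.csv",
                                             "simulate"))
    tab <- utils::read.csv(require_artifact(config, "band_power_table.csv",
                                            "extract"))
    models <- list()
    for (sm in c("male", "female", "pooled"))
      models[[sm]] <- load_model(require_artifact(
        config, paste0("model_", sm, ".json"), "fit"))
    ageband <- load_model(require_artifact(config, "model_age_band.json",
                                           "fit"))

    hc <- config$cohort
    hc$n_per_sex <- config$holdout_n_per_sex
    hc$screening_fail_fraction <- 0
    hc$seed <- stage_seed(config, 2L)
    holdout <- sample_cohort(hc)
    hz <- rbind(
      zscore(models$male,
             holdout$powers[holdout$powers$id %in%
                              holdout$demographics$id[
                                holdout$demographics$sex == "male"], ],
             holdout$demographics),
      zscore(models$female,
             holdout$powers[holdout$powers$id %in%
                              holdout$demographics$id[
                                holdout$demographics$sex == "female"], ],
             holdout$demographics))
    calib <- calibration_report(hz)
    z_ab <- zscore(ageband, holdout$powers, holdout$demographics)
    z_gam <- zscore(models$pooled, holdout$powers, holdout$demographics)
    xcor <- cross_model_correlation(z_gam, z_ab)

    sdm <- sex_difference_map(powers = tab, demographics = demo,
                              threshold = config$threshold,
                              gate_alpha = config$gate_alpha)
    artifacts$sex_difference_map <- write_table(
      sdm, stage_file(config, "sex_difference_map.csv"))

    anom <- holdout
    anom_ids <- anom$demographics$id[anom$demographics$sex == "male"][1:5]
    anom <- inject_anomaly(anom, anom_ids, "theta", montage_1020(), 3)
    contrast <- anomaly_contrast(
      anom, stratified = models[c("male", "female")],
      pooled = models$pooled)

    report <- list(
      seed = config$seed,
      calibration = list(pooled = calib$pooled,
                         n_excluded = calib$n_excluded),
      cross_model_correlation = xcor,
      anomaly_contrast = contrast$summary,
      sex_difference_map = list(
        threshold = config$threshold,
        n_significant = sum(sdm$significant), n_cells = nrow(sdm)))
    f <- stage_file(config, "validation_report.json")
    jsonlite::write_json(report, f, digits = NA, auto_unbox = TRUE,
                         force = TRUE)
    artifacts$validation_report <- f
  }

  invisible(artifacts)
}
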