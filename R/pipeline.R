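# Orchestration: simulate -> filter -> detect-onset -> extract-features
# -> screen -> fit -> evaluate, driven by a flat key=value config file,
# writing every stage table plus a machine-readable manifest.

#' Default run configuration
#'
#' All analysis parameters with their standard values: SIRS thresholds
#' (38/36 degrees C, 90 bpm, 20 breaths/min, 12000/4000 cells/cmm, 2
#' criteria, >5 h episodes, <6 h merge gap), shock rules (SBP < 90
#' mmHg for >= 30 min; fluids > 600 mL from 1 h before the episode to
#' its midpoint), a 48 h feature window, a 168 h (7-day) mortality
#' horizon, significance level 0.05, elastic-net mixing weight 0.5
#' with 3/4/5-fold selection and 5-fold evaluation, and the synthetic
#' cohort defaults (73 patients, nonsurvivor fraction 20/73).
#'
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    n_patients = 73L, nonsurvivor_fraction = 20 / 73, seed = 1L,
    temp_high = 38, temp_low = 36, hr_thresh = 90, rr_thresh = 20,
    wbc_high = 12000, wbc_low = 4000, min_criteria = 2L,
    min_episode_h = 5, merge_gap_h = 6,
    sbp_thresh = 90, min_hypo_min = 30, fluid_pre_h = 1,
    fluid_thresh_ml = 600,
    window_h = 48, mortality_horizon_h = 168,
    alpha = 0.05, alpha_mix = 0.5,
    fold_counts = c(3L, 4L, 5L), eval_folds = 5L, vif_threshold = 5),
    class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored;
#' `fold_counts` may be a comma-separated list. Unknown keys are an
#' error; missing keys take their defaults.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @param overrides Named list overriding file values.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed config line: ", ln,
                                 call. = FALSE)
      key <- trimws(kv[1L])
      val <- trimws(kv[2L])
      if (!key %in% names(cfg)) stop("unknown config key: ", key,
                                     call. = FALSE)
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))
      if (anyNA(num)) stop("non-numeric config value for ", key, ": ",
                           val, call. = FALSE)
      cfg[[key]] <- if (key %in% c("n_patients", "seed", "min_criteria",
                                   "fold_counts", "eval_folds"))
        as.integer(num) else num
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) stop("unknown config key: ", key,
                                   call. = FALSE)
    cfg[[key]] <- overrides[[key]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(format(config[[k]], digits = 17,
                                  scientific = FALSE),
                           collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

config_sirs <- function(cfg) {
  sirs_config(temp_high = cfg$temp_high, temp_low = cfg$temp_low,
              hr_thresh = cfg$hr_thresh, rr_thresh = cfg$rr_thresh,
              wbc_high = cfg$wbc_high, wbc_low = cfg$wbc_low,
              min_criteria = cfg$min_criteria,
              min_episode_h = cfg$min_episode_h,
              merge_gap_h = cfg$merge_gap_h)
}

config_shock <- function(cfg) {
  shock_config(sbp_thresh = cfg$sbp_thresh,
               min_hypo_min = cfg$min_hypo_min,
               fluid_pre_h = cfg$fluid_pre_h,
               fluid_thresh_ml = cfg$fluid_thresh_ml)
}

cohort_paths <- function(dir) {
  c(vitals = file.path(dir, "vitals.csv"),
    fluids = file.path(dir, "fluids.csv"),
    outcomes = file.path(dir, "outcomes.csv"))
}

write_stage_csv <- function(df, path) {
  data.table::fwrite(data.table::as.data.table(df), path, na = "")
  path
}

#' Run the whole pipeline
#'
#' Simulates (or reads) a cohort, applies the inclusion filter,
#' detects shock onsets, drops patients without a labeled onset,
#' extracts the 135 features with mean imputation, screens them
#' univariately, builds the elastic-net mortality model and evaluates
#' its cross-validated AUC. Every stage writes its table under
#' `out_dir`, and `manifest.json` records the config, per-stage
#' attrition and the MD5 of every output so that identical inputs
#' give identical manifests. When no patient shows an onset, the
#' screen and model stages are skipped with an explanatory manifest
#' entry.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @param cohort_dir Optional directory with existing
#'   `vitals.csv`/`fluids.csv`/`outcomes.csv`; when `NULL` a synthetic
#'   cohort is simulated per the config.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         cohort_dir = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("shockwatch")),
                   config = unclass(config), stages = list())
  outputs <- character()

  # -- simulate / load ---------------------------------------------------
  if (is.null(cohort_dir)) {
    spec <- cohort_spec(n_patients = config$n_patients,
                        nonsurvivor_fraction = config$nonsurvivor_fraction,
                        seed = config$seed)
    gen <- generate_cohort(spec)
    records <- gen$records
    paths <- cohort_paths(out_dir)
    write_cohort(records, paths["vitals"], paths["fluids"],
                 paths["outcomes"])
    truth_path <- file.path(out_dir, "ground_truth.csv")
    write_stage_csv(gen$truth$truth, truth_path)
    writeLines(gen$truth$planted_features,
               file.path(out_dir, "planted_features.txt"))
    outputs <- c(outputs, paths, truth_path,
                 file.path(out_dir, "planted_features.txt"))
    manifest$stages$simulate <- list(n_patients = length(records))
  } else {
    paths <- cohort_paths(cohort_dir)
    records <- read_cohort(paths["vitals"], paths["fluids"],
                           paths["outcomes"])
    manifest$stages$load <- list(n_patients = length(records),
                                 cohort_dir = cohort_dir)
  }

  # -- inclusion filter --------------------------------------------------
  flt <- filter_cohort(records)
  incl <- data.frame(
    patient_id = vapply(flt$reports, `[[`, "", "patient_id"),
    included = vapply(flt$reports, `[[`, TRUE, "included"),
    failed_rules = vapply(flt$reports, function(r)
      paste(r$failed_rules, collapse = ";"), ""))
  outputs <- c(outputs, write_stage_csv(incl,
                 file.path(out_dir, "inclusion.csv")))
  records <- flt$records
  manifest$stages$filter <- list(n_included = length(records),
                                 n_excluded = sum(!incl$included))

  # -- onset detection ---------------------------------------------------
  det <- detect_cohort_onsets(records, config_sirs(config),
                              config_shock(config))
  outputs <- c(outputs,
               write_stage_csv(det$onsets, file.path(out_dir, "onsets.csv")),
               write_stage_csv(det$episodes,
                               file.path(out_dir, "episodes.csv")))
  labeled <- det$onsets[det$onsets$reason == "labeled", ]
  manifest$stages$detect_onset <-
    list(n_labeled = nrow(labeled),
         n_dropped = nrow(det$onsets) - nrow(labeled),
         dropped_reasons = as.list(table(
           det$onsets$reason[det$onsets$reason != "labeled"])))

  if (nrow(labeled) == 0L) {
    manifest$stages$skipped <- paste("no patient yielded a labeled",
                                     "shock onset; downstream stages",
                                     "skipped")
    manifest$outputs <- as.list(tools::md5sum(sort(unique(outputs))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(manifest))
  }

  # -- feature extraction ------------------------------------------------
  rec_by_id <- setNames(records, vapply(records, `[[`, "", "patient_id"))
  fvs <- lapply(seq_len(nrow(labeled)), function(i) {
    extract_features(rec_by_id[[labeled$patient_id[i]]],
                     labeled$onset_h[i], width_h = config$window_h,
                     horizon_h = config$mortality_horizon_h)
  })
  raw <- data.frame(patient_id = vapply(fvs, `[[`, "", "patient_id"),
                    label = vapply(fvs, `[[`, "", "label"))
  raw <- cbind(raw, t(vapply(fvs, function(f) f$values,
                             numeric(135))))
  outputs <- c(outputs, write_stage_csv(raw,
                 file.path(out_dir, "features_raw.csv")))
  cm <- assemble_matrix(fvs)
  imp <- cbind(raw[, c("patient_id", "label")], as.data.frame(cm$x))
  outputs <- c(outputs, write_stage_csv(imp,
                 file.path(out_dir, "features_imputed.csv")))
  manifest$stages$extract_features <-
    list(n_patients = nrow(cm$x), n_features = ncol(cm$x),
         missing_cells = sum(cm$missing_mask),
         missing_fraction = round(mean(cm$missing_mask), 5))

  if (all(cm$labels == "S") || all(cm$labels == "NS")) {
    manifest$stages$skipped <- paste("only one outcome class present;",
                                     "screen and model stages skipped")
    manifest$outputs <- as.list(tools::md5sum(sort(unique(outputs))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(manifest))
  }

  # -- univariate screen -------------------------------------------------
  scr <- screen_features(cm, alpha = config$alpha)
  outputs <- c(outputs, write_stage_csv(scr,
                 file.path(out_dir, "univariate_screen.csv")))
  manifest$stages$screen <- list(n_significant = sum(scr$significant))

  # -- model fit + evaluation -------------------------------------------
  model <- build_mortality_model(cm, alpha_mix = config$alpha_mix,
                                 fold_counts = config$fold_counts,
                                 seed = config$seed,
                                 vif_threshold = config$vif_threshold,
                                 eval_folds = config$eval_folds)
  coefs <- data.frame(
    feature = model$selected_features,
    coefficient = unname(model$coefficients[model$selected_features]),
    vif = unname(model$vif[model$selected_features]),
    significant_univariate =
      scr$significant[match(model$selected_features, scr$feature)])
  outputs <- c(outputs, write_stage_csv(coefs,
                 file.path(out_dir, "model_coefficients.csv")))
  report <- list(selected_features = model$selected_features,
                 coefficients = as.list(model$coefficients),
                 vif = as.list(model$vif),
                 removed_by_vif = model$removed_by_vif,
                 mse = model$mse,
                 auc_mean = model$auc_mean, auc_sd = model$auc_sd,
                 chosen_folds = model$chosen_folds,
                 alpha_mix = model$alpha_mix,
                 cv = lapply(model$cv_curves, function(cv)
                   list(folds = cv$folds, lambda_min = cv$lambda_min,
                        lambda_1se = cv$lambda_1se,
                        error_min = cv$error_min,
                        error_1se = cv$error_1se)))
  jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  outputs <- c(outputs, file.path(out_dir, "model_report.json"))
  eval_df <- data.frame(fold = seq_along(model$auc_folds),
                        auc = model$auc_folds)
  outputs <- c(outputs, write_stage_csv(eval_df,
                 file.path(out_dir, "evaluation_auc.csv")))
  manifest$stages$fit <- list(n_selected = length(model$selected_features),
                              n_removed_by_vif =
                                length(model$removed_by_vif),
                              chosen_folds = model$chosen_folds,
                              mse = model$mse)
  manifest$stages$evaluate <- list(auc_mean = model$auc_mean,
                                   auc_sd = model$auc_sd)

  manifest$outputs <- as.list(tools::md5sum(sort(unique(unname(outputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
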