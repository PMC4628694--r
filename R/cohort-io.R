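#' @useDynLib shockwatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif rexp sd setNames p.adjust
#'   wilcox.test lm coef predict rbinom
#' @importFrom utils head tail
NULL

# tell data.table that this package uses its [ semantics
.datatable.aware <- TRUE

#' Canonical monitored variables
#'
#' The 15 variables the pipeline knows about: seven derived from
#' continuous hemodynamic monitoring (SBP, DBP, MAP in mmHg; HR in bpm;
#' RR in breaths/min; CVP in mmHg; CO in L/min) and eight clinical /
#' laboratory parameters (T in degrees C, arterial pH, creatinine in
#' mg/dL, glucose in mg/dL, lactate in mmol/L, hematocrit in %, WBC in
#' cells/cmm, SpO2 in %).
#'
#' @format Character vector of length 15.
#' @export
VITAL_VARIABLES <- c("SBP", "DBP", "MAP", "HR", "RR", "CVP", "CO",
                     "T", "pH", "creatinine", "glucose", "lactate",
                     "hematocrit", "WBC", "SpO2")

#' Construct a vital-sign series
#'
#' A `vital_series` holds one irregularly sampled clinical variable for
#' one patient: sample times in hours since ICU admission and the
#' measured values. Times must be strictly increasing (no duplicate
#' timestamps within a variable) and values finite.
#'
#' @param variable One of [VITAL_VARIABLES].
#' @param times Numeric vector, hours from ICU admission, non-negative,
#'   strictly increasing.
#' @param values Numeric vector, same length as `times`, finite.
#' @return An object of class `vital_series`.
#' @export
vital_series <- function(variable, times, values) {
  if (!is.character(variable) || length(variable) != 1L ||
      !(variable %in% VITAL_VARIABLES)) {
    stop("unknown variable: ", paste(variable, collapse = ","),
         " (must be one of the 15 canonical names)", call. = FALSE)
  }
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have the same length for variable ",
         variable, call. = FALSE)
  }
  if (length(times)) {
    if (anyNA(times) || any(times < 0)) {
      stop("times must be non-negative and non-missing (", variable, ")",
           call. = FALSE)
    }
    if (any(diff(times) <= 0)) {
      stop("times must be strictly increasing with no duplicates (",
           variable, ")", call. = FALSE)
    }
    if (!all(is.finite(values))) {
      stop("values must be finite (", variable, ")", call. = FALSE)
    }
  }
  structure(list(variable = variable, times = times, values = values),
            class = "vital_series")
}

#' Construct a patient record
#'
#' Bundles all series, intravenous fluid events, ICU stay duration and
#' outcome for one patient. Fluid events are ordered by time; volumes
#' are in mL and must be non-negative. `death_time_h` is `NA` for
#' patients with no recorded death.
#'
#' @param patient_id Opaque string identifier.
#' @param series Named list of [vital_series()] objects (names are the
#'   variable names); variables may be absent.
#' @param fluids Data frame with columns `time_h`, `volume_ml`.
#' @param icu_stay_h ICU stay length, hours, > 0.
#' @param death_time_h Hours from ICU admission to death, or `NA`.
#' @param age_years Age at admission, >= 18.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, series = list(),
                           fluids = data.frame(time_h = numeric(),
                                               volume_ml = numeric()),
                           icu_stay_h, death_time_h = NA_real_,
                           age_years = 60) {
  patient_id <- as.character(patient_id)
  stopifnot(length(patient_id) == 1L, nzchar(patient_id))
  icu_stay_h <- as.numeric(icu_stay_h)
  if (!is.finite(icu_stay_h) || icu_stay_h <= 0) {
    stop("icu_stay_h must be a positive number (patient ", patient_id, ")",
         call. = FALSE)
  }
  death_time_h <- as.numeric(death_time_h)
  if (!is.na(death_time_h) && death_time_h < 0) {
    stop("death_time_h must be >= 0 (patient ", patient_id, ")",
         call. = FALSE)
  }
  age_years <- as.numeric(age_years)
  if (!is.finite(age_years) || age_years < 18) {
    stop("age_years must be >= 18 (patient ", patient_id, ")",
         call. = FALSE)
  }
  if (length(series)) {
    if (is.null(names(series)) || anyDuplicated(names(series))) {
      stop("series must be a uniquely named list (patient ", patient_id,
           ")", call. = FALSE)
    }
    for (nm in names(series)) {
      s <- series[[nm]]
      if (!inherits(s, "vital_series") || !identical(s$variable, nm)) {
        stop("series entry ", nm, " must be a vital_series for that ",
             "variable (patient ", patient_id, ")", call. = FALSE)
      }
      if (length(s$times) && max(s$times) > icu_stay_h + 1e-9) {
        stop("series ", nm, " has timestamps beyond icu_stay_h (patient ",
             patient_id, ")", call. = FALSE)
      }
    }
  }
  fluids <- as.data.frame(fluids)
  if (!all(c("time_h", "volume_ml") %in% names(fluids))) {
    stop("fluids must have columns time_h, volume_ml (patient ",
         patient_id, ")", call. = FALSE)
  }
  fluids <- fluids[order(fluids$time_h), c("time_h", "volume_ml"),
                   drop = FALSE]
  rownames(fluids) <- NULL
  if (nrow(fluids) && (anyNA(fluids$volume_ml) || any(fluids$volume_ml < 0))) {
    stop("fluid volumes must be non-negative (patient ", patient_id, ")",
         call. = FALSE)
  }
  structure(list(patient_id = patient_id, series = series,
                 fluids = fluids, icu_stay_h = icu_stay_h,
                 death_time_h = death_time_h, age_years = age_years),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$patient_id, "\n")
  cat("  ICU stay:", format(x$icu_stay_h), "h;",
      if (is.na(x$death_time_h)) "no recorded death" else
        paste0("death at ", format(x$death_time_h), " h"), "\n")
  cat("  series:", paste(names(x$series), collapse = ", "), "\n")
  cat("  fluid events:", nrow(x$fluids), "\n")
  invisible(x)
}

# ---- long-format cohort files ------------------------------------------

read_table_checked <- function(path, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = NULL, data.table = TRUE,
                          na.strings = c("", "NA"))
  if (!identical(names(dt), expected_cols)) {
    stop(path, ": expected header ", paste(expected_cols, collapse = ","),
         " but found ", paste(names(dt), collapse = ","), call. = FALSE)
  }
  dt
}

fail_row <- function(path, line, field, msg) {
  # line is 1-based over data rows; +1 accounts for the header
  stop(path, " line ", line + 1L, ", field '", field, "': ", msg,
       call. = FALSE)
}

#' Read a cohort from the three long-format files
#'
#' The cohort is stored as three comma-delimited text files:
#' * vitals: `patient_id,variable,time_h,value`
#' * fluids: `patient_id,time_h,volume_ml`
#' * outcomes: `patient_id,age_years,icu_stay_h,death_time_h`
#'   (empty `death_time_h` for patients without a recorded death)
#'
#' One [patient_record()] is built per row of the outcomes file; vitals
#' and fluids rows for unknown patients, unknown variable names,
#' non-numeric fields, or duplicated `(patient, variable, time)` keys
#' raise an error naming the file and line.
#'
#' @param vitals_path,fluids_path,outcomes_path File paths.
#' @return List of `patient_record`, ordered by the outcomes file.
#' @export
read_cohort <- function(vitals_path, fluids_path, outcomes_path) {
  patient_id <- variable <- NULL # data.table NSE
  out <- read_table_checked(outcomes_path,
                            c("patient_id", "age_years", "icu_stay_h",
                              "death_time_h"))
  vit <- read_table_checked(vitals_path,
                            c("patient_id", "variable", "time_h", "value"))
  flu <- read_table_checked(fluids_path,
                            c("patient_id", "time_h", "volume_ml"))

  out[, patient_id := as.character(patient_id)]
  if (anyDuplicated(out$patient_id)) {
    stop(outcomes_path, ": duplicated patient_id ",
         out$patient_id[duplicated(out$patient_id)][1L], call. = FALSE)
  }
  known <- out$patient_id

  if (nrow(vit)) {
    vit[, patient_id := as.character(patient_id)]
    vit[, variable := as.character(variable)]
    bad <- which(!(vit$variable %in% VITAL_VARIABLES))
    if (length(bad)) {
      fail_row(vitals_path, bad[1L], "variable",
               paste0("unknown variable '", vit$variable[bad[1L]], "'"))
    }
    bad <- which(!is.finite(vit$time_h))
    if (length(bad)) fail_row(vitals_path, bad[1L], "time_h",
                              "missing or non-numeric time")
    bad <- which(!is.finite(vit$value))
    if (length(bad)) fail_row(vitals_path, bad[1L], "value",
                              "missing or non-numeric value")
    bad <- which(!(vit$patient_id %in% known))
    if (length(bad)) fail_row(vitals_path, bad[1L], "patient_id",
                              "patient absent from outcomes file")
    dup <- which(duplicated(vit[, c("patient_id", "variable", "time_h")]))
    if (length(dup)) {
      fail_row(vitals_path, dup[1L], "time_h",
               "duplicated (patient, variable, time)")
    }
  }
  if (nrow(flu)) {
    flu[, patient_id := as.character(patient_id)]
    bad <- which(!is.finite(flu$time_h))
    if (length(bad)) fail_row(fluids_path, bad[1L], "time_h",
                              "missing or non-numeric time")
    bad <- which(!is.finite(flu$volume_ml) | flu$volume_ml < 0)
    if (length(bad)) fail_row(fluids_path, bad[1L], "volume_ml",
                              "missing, non-numeric or negative volume")
    bad <- which(!(flu$patient_id %in% known))
    if (length(bad)) fail_row(fluids_path, bad[1L], "patient_id",
                              "patient absent from outcomes file")
  }

  vit_split <- if (nrow(vit)) split(vit, by = "patient_id") else list()
  flu_split <- if (nrow(flu)) split(flu, by = "patient_id") else list()

  lapply(seq_len(nrow(out)), function(i) {
    pid <- out$patient_id[i]
    pv <- vit_split[[pid]]
    series <- list()
    if (!is.null(pv)) {
      for (v in unique(pv$variable)) {
        sub <- pv[pv$variable == v, ]
        o <- order(sub$time_h)
        series[[v]] <- vital_series(v, sub$time_h[o], sub$value[o])
      }
      series <- series[intersect(VITAL_VARIABLES, names(series))]
    }
    pf <- flu_split[[pid]]
    fl <- if (is.null(pf)) data.frame(time_h = numeric(),
                                      volume_ml = numeric())
          else data.frame(time_h = pf$time_h, volume_ml = pf$volume_ml)
    patient_record(pid, series, fl,
                   icu_stay_h = out$icu_stay_h[i],
                   death_time_h = out$death_time_h[i],
                   age_years = out$age_years[i])
  })
}

#' Write a cohort to the three long-format files
#'
#' Inverse of [read_cohort()]. Rows are emitted in deterministic order
#' (patient, then variable in canonical order, then time) so repeated
#' writes of the same cohort are byte-identical.
#'
#' @param records List of [patient_record()].
#' @param vitals_path,fluids_path,outcomes_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_cohort <- function(records, vitals_path, fluids_path, outcomes_path) {
  stopifnot(is.list(records))
  for (r in records) {
    if (!inherits(r, "patient_record")) {
      stop("records must be patient_record objects", call. = FALSE)
    }
  }
  vit <- data.table::rbindlist(lapply(records, function(r) {
    if (!length(r$series)) return(NULL)
    data.table::rbindlist(lapply(r$series[intersect(VITAL_VARIABLES,
                                                    names(r$series))],
      function(s) data.table::data.table(patient_id = r$patient_id,
                                         variable = s$variable,
                                         time_h = s$times,
                                         value = s$values)))
  }))
  if (!nrow(vit)) {
    vit <- data.table::data.table(patient_id = character(),
                                  variable = character(),
                                  time_h = numeric(), value = numeric())
  }
  flu <- data.table::rbindlist(lapply(records, function(r) {
    if (!nrow(r$fluids)) return(NULL)
    data.table::data.table(patient_id = r$patient_id,
                           time_h = r$fluids$time_h,
                           volume_ml = r$fluids$volume_ml)
  }))
  if (!nrow(flu)) {
    flu <- data.table::data.table(patient_id = character(),
                                  time_h = numeric(), volume_ml = numeric())
  }
  out <- data.table::data.table(
    patient_id = vapply(records, `[[`, "", "patient_id"),
    age_years = vapply(records, `[[`, 0, "age_years"),
    icu_stay_h = vapply(records, `[[`, 0, "icu_stay_h"),
    death_time_h = vapply(records, `[[`, 0, "death_time_h"))
  data.table::fwrite(vit, vitals_path, na = "")
  data.table::fwrite(flu, fluids_path, na = "")
  data.table::fwrite(out, outcomes_path, na = "")
  invisible(c(vitals = vitals_path, fluids = fluids_path,
              outcomes = outcomes_path))
}

#' Apply the cohort inclusion criteria
#'
#' A record is retained when the heart rate, temperature, systolic
#' blood pressure and respiratory rate series each carry at least 10
#' measurements over the ICU stay, the white-blood-cell count at least
#' 2, and the ICU stay is at least 48 h. Patients with a shorter stay
#' or sparser records are excluded. A missing series counts as zero
#' measurements.
#'
#' @param record A [patient_record()].
#' @return A list of class `inclusion_report` with `patient_id`,
#'   `included` (logical) and `failed_rules` (character; empty iff
#'   included).
#' @export
apply_inclusion_criteria <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  n_of <- function(v) {
    s <- record$series[[v]]
    if (is.null(s)) 0L else length(s$times)
  }
  failed <- character()
  if (n_of("HR") < 10L) failed <- c(failed, "min_hr_count")
  if (n_of("T") < 10L) failed <- c(failed, "min_t_count")
  if (n_of("SBP") < 10L) failed <- c(failed, "min_sbp_count")
  if (n_of("RR") < 10L) failed <- c(failed, "min_rr_count")
  if (n_of("WBC") < 2L) failed <- c(failed, "min_wbc_count")
  if (record$icu_stay_h < 48) failed <- c(failed, "min_stay")
  structure(list(patient_id = record$patient_id,
                 included = length(failed) == 0L,
                 failed_rules = failed),
            class = "inclusion_report")
}

#' Filter a cohort by the inclusion criteria
#'
#' @param records List of [patient_record()].
#' @return List with `records` (the retained records) and `reports`
#'   (one [apply_inclusion_criteria()] report per input record).
#' @export
filter_cohort <- function(records) {
  reports <- lapply(records, apply_inclusion_criteria)
  keep <- vapply(reports, `[[`, TRUE, "included")
  list(records = records[keep], reports = reports)
}
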