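#' Names of the nine summary statistics
#'
#' In canonical order: mean, std (sample standard deviation), min, max,
#' median, kurtosis (Pearson, non-excess, so a Gaussian tends to 3),
#' skewness (population moment ratio), slope (ordinary least squares
#' against time, units per hour) and delta (last minus first observed
#' value in the window).
#'
#' @format Character vector of length 9.
#' @export
FEATURE_STATS <- c("mean", "std", "min", "max", "median",
                   "kurtosis", "skewness", "slope", "delta")

#' The 135 feature names
#'
#' All combinations `<stat>_<variable>` of the 9 statistics and the 15
#' monitored variables, ordered variable-major (all statistics of SBP,
#' then DBP, ...), the order used in every report table.
#'
#' @return Character vector of length 135.
#' @export
feature_names <- function() {
  as.vector(vapply(VITAL_VARIABLES,
                   function(v) paste0(FEATURE_STATS, "_", v),
                   character(length(FEATURE_STATS))))
}

#' Restrict a record's series to the post-onset analysis window
#'
#' Keeps samples with time in `[onset_h, onset_h + width_h]` (both
#' endpoints included) and re-expresses times as hours since onset.
#' Variables with no sample in the window are dropped.
#'
#' @param record A [patient_record()].
#' @param onset_h Shock onset, hours from admission.
#' @param width_h Window width, hours (default 48).
#' @return Named list of [vital_series()].
#' @export
window_series <- function(record, onset_h, width_h = 48) {
  stopifnot(inherits(record, "patient_record"), is.finite(onset_h),
            width_h > 0)
  out <- list()
  for (nm in names(record$series)) {
    s <- record$series[[nm]]
    keep <- s$times >= onset_h & s$times <= onset_h + width_h
    if (any(keep)) {
      out[[nm]] <- vital_series(nm, s$times[keep] - onset_h,
                                s$values[keep])
    }
  }
  out
}

#' Summary statistics of one windowed series
#'
#' Computes the nine indexes. Minimum sample counts: 1 for
#' mean/min/max/median, 2 for std/slope/delta, 3 for skewness, 4 for
#' kurtosis; below these the statistic is `NA`. A zero-variance series
#' has undefined skewness and kurtosis (`NA`), slope 0 and delta 0.
#' Skewness is the population moment ratio m3/m2^1.5 and kurtosis the
#' non-excess m4/m2^2; std is the sample (n-1) standard deviation;
#' slope is the unweighted OLS slope of value on time in units/hour.
#'
#' @param series A [vital_series()] with times in hours since onset.
#' @return Named numeric vector over [FEATURE_STATS] (may contain `NA`).
#' @export
summarize_series <- function(series) {
  stopifnot(inherits(series, "vital_series"))
  v <- series$values
  t <- series$times
  n <- length(v)
  out <- setNames(rep(NA_real_, length(FEATURE_STATS)), FEATURE_STATS)
  if (n == 0L) return(out)
  out["mean"] <- mean(v)
  out["min"] <- min(v)
  out["max"] <- max(v)
  out["median"] <- median(v)
  if (n >= 2L) {
    out["std"] <- sd(v)
    out["delta"] <- v[n] - v[1L]
    m2t <- mean((t - mean(t))^2)
    out["slope"] <- if (m2t > 0) {
      sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
    } else 0
  }
  m2 <- mean((v - mean(v))^2)
  if (m2 > 0) {
    if (n >= 3L) out["skewness"] <- mean((v - mean(v))^3) / m2^1.5
    if (n >= 4L) out["kurtosis"] <- mean((v - mean(v))^4) / m2^2
  } else if (n >= 2L) {
    out["slope"] <- 0
    out["delta"] <- 0
  }
  out
}

#' Extract the 135-index feature vector of one patient
#'
#' Applies [window_series()] and [summarize_series()] to every
#' variable; absent variables yield `NA` for their nine features. The
#' 7-day mortality label is `NS` when the patient died within
#' `horizon_h` hours (default 168 = 7 days) after onset, `S` otherwise.
#'
#' @param record A [patient_record()].
#' @param onset_h Shock onset, hours from admission.
#' @param width_h Analysis window width, hours.
#' @param horizon_h Mortality horizon, hours.
#' @return A list of class `feature_vector`: `patient_id`, `values`
#'   (named numeric of length 135, `NA` allowed), `label` (`"S"` or
#'   `"NS"`).
#' @export
extract_features <- function(record, onset_h, width_h = 48,
                             horizon_h = 168) {
  win <- window_series(record, onset_h, width_h)
  vals <- setNames(rep(NA_real_, 135L), feature_names())
  for (nm in names(win)) {
    s <- summarize_series(win[[nm]])
    vals[paste0(FEATURE_STATS, "_", nm)] <- s[FEATURE_STATS]
  }
  label <- if (!is.na(record$death_time_h) &&
               record$death_time_h <= onset_h + horizon_h) "NS" else "S"
  structure(list(patient_id = record$patient_id, values = vals,
                 label = label),
            class = "feature_vector")
}

#' Assemble the cohort feature matrix with mean imputation
#'
#' Stacks feature vectors into a patients x 135 matrix, records which
#' cells were missing, and replaces each missing cell by the
#' across-patient mean of the observed values of that feature (so
#' column means are unchanged by imputation). A feature observed for no
#' patient at all is an error.
#'
#' @param feature_vectors List of [extract_features()] results (>= 2).
#' @return A list of class `cohort_matrix`: `x` (imputed numeric
#'   matrix), `feature_names`, `patient_ids`, `labels` (factor S/NS),
#'   `missing_mask` (logical matrix, TRUE where imputed),
#'   `imputed_means` (named numeric).
#' @export
assemble_matrix <- function(feature_vectors) {
  stopifnot(is.list(feature_vectors), length(feature_vectors) >= 2L)
  fn <- feature_names()
  x <- t(vapply(feature_vectors, function(fv) {
    stopifnot(inherits(fv, "feature_vector"))
    fv$values[fn]
  }, numeric(length(fn))))
  colnames(x) <- fn
  rownames(x) <- NULL
  ids <- vapply(feature_vectors, `[[`, "", "patient_id")
  labels <- factor(vapply(feature_vectors, `[[`, "", "label"),
                   levels = c("S", "NS"))
  mask <- is.na(x)
  all_missing <- colSums(!mask) == 0L
  if (any(all_missing)) {
    stop("feature observed for no patient: ",
         paste(fn[all_missing], collapse = ", "), call. = FALSE)
  }
  means <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(mask) > 0L)) {
    x[mask[, j], j] <- means[j]
  }
  structure(list(x = x, feature_names = fn, patient_ids = ids,
                 labels = labels, missing_mask = mask,
                 imputed_means = means),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("<cohort_matrix> ", nrow(x$x), " patients x ", ncol(x$x),
      " features; ", sum(x$labels == "NS"), " nonsurvivors; ",
      sum(x$missing_mask), " imputed cells\n", sep = "")
  invisible(x)
}
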