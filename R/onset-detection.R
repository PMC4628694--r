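#' SIRS episode detection settings
#'
#' Thresholds of the four SIRS criteria and the temporal rules that
#' turn criterion-level abnormality into episodes: temperature > 38 or
#' < 36 degrees C, heart rate > 90 bpm, respiratory rate > 20
#' breaths/min, white-blood-cell count > 12,000 or < 4,000 cells/cmm.
#' An episode must last more than `min_episode_h` hours to count, and
#' abnormal intervals less than `merge_gap_h` hours apart are merged
#' into a single episode. `min_criteria` is the number of criteria that
#' must be abnormal simultaneously; the conventional SIRS definition
#' uses 2 of 4 (the default), and 4 can be requested to demand all
#' criteria at once.
#'
#' @param temp_high,temp_low,hr_thresh,rr_thresh,wbc_high,wbc_low
#'   Criterion thresholds (strict comparisons as printed above).
#' @param min_criteria Integer in 1..4.
#' @param min_episode_h Episodes with duration <= this are discarded.
#' @param merge_gap_h Intervals closer than this are merged.
#' @return A list of class `sirs_config`.
#' @export
sirs_config <- function(temp_high = 38, temp_low = 36, hr_thresh = 90,
                        rr_thresh = 20, wbc_high = 12000, wbc_low = 4000,
                        min_criteria = 2L, min_episode_h = 5,
                        merge_gap_h = 6) {
  stopifnot(temp_low < temp_high, wbc_low < wbc_high,
            temp_low > 0, hr_thresh > 0, rr_thresh > 0, wbc_low > 0,
            min_criteria %in% 1:4, min_episode_h > 0, merge_gap_h > 0)
  structure(list(temp_high = temp_high, temp_low = temp_low,
                 hr_thresh = hr_thresh, rr_thresh = rr_thresh,
                 wbc_high = wbc_high, wbc_low = wbc_low,
                 min_criteria = as.integer(min_criteria),
                 min_episode_h = min_episode_h,
                 merge_gap_h = merge_gap_h),
            class = "sirs_config")
}

#' Shock onset detection settings
#'
#' Prolonged hypotension is systolic blood pressure below `sbp_thresh`
#' (strict) held for at least `min_hypo_min` minutes. An episode is
#' classified as sepsis-induced hypotension when the fluid volume
#' administered from `fluid_pre_h` hours before its start to halfway
#' through the episode exceeds `fluid_thresh_ml` (strict).
#'
#' @param sbp_thresh mmHg, default 90.
#' @param min_hypo_min Minutes, default 30.
#' @param fluid_pre_h Hours, default 1.
#' @param fluid_thresh_ml mL, default 600.
#' @return A list of class `shock_config`.
#' @export
shock_config <- function(sbp_thresh = 90, min_hypo_min = 30,
                         fluid_pre_h = 1, fluid_thresh_ml = 600) {
  stopifnot(sbp_thresh > 0, min_hypo_min > 0, fluid_pre_h > 0,
            fluid_thresh_ml > 0)
  structure(list(sbp_thresh = sbp_thresh, min_hypo_min = min_hypo_min,
                 fluid_pre_h = fluid_pre_h,
                 fluid_thresh_ml = fluid_thresh_ml),
            class = "shock_config")
}

# comparisons on durations/gaps use a tolerance far below any clinical
# charting resolution, so that values equal to a threshold up to float
# error behave as the exact arithmetic would
.time_eps <- 1e-9

empty_episodes <- function() {
  data.frame(kind = character(), start_h = numeric(), end_h = numeric(),
             contributing = character(), fluid_ml = numeric(),
             stringsAsFactors = FALSE)
}

episode_frame <- function(kind, start_h, end_h, contributing = NA_character_,
                          fluid_ml = NA_real_) {
  data.frame(kind = kind, start_h = start_h, end_h = end_h,
             contributing = contributing, fluid_ml = fluid_ml,
             stringsAsFactors = FALSE)
}

#' Sample-and-hold intervals satisfying a predicate
#'
#' Each measurement's value is held from its own timestamp until the
#' next measurement of the same variable; the last value is held to the
#' end of the ICU stay. Returns the maximal intervals over which the
#' held value satisfies `predicate`, as a data frame with columns
#' `start_h`, `end_h`.
#'
#' @param series A [vital_series()] (may be empty: returns no intervals).
#' @param predicate Vectorised function values -> logical.
#' @param end_h End of stay, hours; intervals never extend beyond it.
#' @return Data frame `start_h`, `end_h`, possibly zero rows.
#' @export
hold_intervals <- function(series, predicate, end_h) {
  stopifnot(inherits(series, "vital_series"), is.function(predicate),
            is.finite(end_h))
  t <- series$times
  if (!length(t)) return(data.frame(start_h = numeric(), end_h = numeric()))
  ok <- as.logical(predicate(series$values))
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(data.frame(start_h = numeric(), end_h = numeric()))
  starts <- t[idx_start[keep]]
  ends <- ifelse(idx_end[keep] < length(t), t[pmin(idx_end[keep] + 1L,
                                                   length(t))], end_h)
  d <- data.frame(start_h = starts, end_h = pmin(ends, end_h))
  d[d$end_h > d$start_h, , drop = FALSE]
}

# Merge intervals whose gap is < gap_h (strict). Overlapping or touching
# intervals always merge. Input need not be disjoint; output is sorted,
# disjoint, pairwise separated by >= gap_h.
merge_gapped <- function(starts, ends, gap_h) {
  if (!length(starts)) return(list(start = numeric(), end = numeric(),
                                   members = list()))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  members <- list(); cur <- o[1L]
  out_s <- numeric(); out_e <- numeric()
  if (length(starts) > 1L) {
    for (i in 2L:length(starts)) {
      if (starts[i] - me < gap_h - .time_eps) {
        me <- max(me, ends[i]); cur <- c(cur, o[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        members <- c(members, list(cur))
        ms <- starts[i]; me <- ends[i]; cur <- o[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  members <- c(members, list(cur))
  list(start = out_s, end = out_e, members = members)
}

sirs_criteria <- function(config) {
  list(
    temperature = list(var = "T",
      pred = function(v) v > config$temp_high | v < config$temp_low),
    heart_rate = list(var = "HR",
      pred = function(v) v > config$hr_thresh),
    respiratory_rate = list(var = "RR",
      pred = function(v) v > config$rr_thresh),
    wbc = list(var = "WBC",
      pred = function(v) v > config$wbc_high | v < config$wbc_low))
}

#' Detect SIRS abnormality episodes
#'
#' Turns the four SIRS criteria into abnormality episodes in four
#' steps. (1) Each criterion's abnormal intervals are computed under
#' sample-and-hold semantics. (2) Intervals where at least
#' `min_criteria` criteria are simultaneously abnormal are located.
#' (3) Each such interval's start is backtracked to the earliest time
#' from which at least one contributing criterion is continuously
#' abnormal into the interval, so an episode begins at the first
#' measured parameter that met its criterion, not at the time the
#' criterion count was first reached. (4) Intervals less than
#' `merge_gap_h` apart are merged, and merged episodes lasting no more
#' than `min_episode_h` are discarded.
#'
#' @param record A [patient_record()].
#' @param config A [sirs_config()].
#' @return Data frame of episodes (`kind = "abnormality"`) with columns
#'   `kind`, `start_h`, `end_h`, `contributing` (comma-joined criterion
#'   names), `fluid_ml` (`NA`).
#' @export
detect_abnormality_episodes <- function(record, config = sirs_config()) {
  stopifnot(inherits(record, "patient_record"),
            inherits(config, "sirs_config"))
  stay <- record$icu_stay_h
  crits <- sirs_criteria(config)
  crit_iv <- lapply(crits, function(cr) {
    s <- record$series[[cr$var]]
    if (is.null(s)) data.frame(start_h = numeric(), end_h = numeric())
    else hold_intervals(s, cr$pred, stay)
  })

  all_iv <- do.call(rbind, lapply(names(crit_iv), function(nm) {
    d <- crit_iv[[nm]]
    if (!nrow(d)) return(NULL)
    cbind(d, criterion = nm, stringsAsFactors = FALSE)
  }))
  if (is.null(all_iv) || !nrow(all_iv)) return(empty_episodes())

  # elementary segments between all interval endpoints; count coverage
  bp <- sort(unique(c(all_iv$start_h, all_iv$end_h)))
  if (length(bp) < 2L) return(empty_episodes())
  seg_s <- bp[-length(bp)]
  seg_e <- bp[-1L]
  count <- integer(length(seg_s))
  for (k in seq_len(nrow(all_iv))) {
    hit <- all_iv$start_h[k] <= seg_s & all_iv$end_h[k] >= seg_e
    count <- count + hit
  }
  met <- count >= config$min_criteria
  if (!any(met)) return(empty_episodes())
  r <- rle(met)
  iend <- cumsum(r$lengths)
  istart <- iend - r$lengths + 1L
  keep <- which(r$values)
  met_s <- seg_s[istart[keep]]
  met_e <- seg_e[iend[keep]]

  # backtrack each start through any criterion continuously abnormal
  # into the interval (covers the start and extends past it)
  bt_s <- vapply(seq_along(met_s), function(i) {
    s <- met_s[i]
    cover <- all_iv$start_h <= s & all_iv$end_h > s
    if (any(cover)) min(c(s, all_iv$start_h[cover])) else s
  }, 0)

  m <- merge_gapped(bt_s, met_e, config$merge_gap_h)
  dur_ok <- (m$end - m$start) > config$min_episode_h + .time_eps
  if (!any(dur_ok)) return(empty_episodes())
  st <- m$start[dur_ok]; en <- m$end[dur_ok]
  contrib <- vapply(seq_along(st), function(i) {
    ov <- all_iv$start_h < en[i] & all_iv$end_h > st[i]
    paste(sort(unique(all_iv$criterion[ov])), collapse = ",")
  }, "")
  episode_frame("abnormality", st, en, contributing = contrib)
}

#' Detect prolonged hypotension episodes
#'
#' Maximal sample-and-hold intervals with systolic blood pressure below
#' `sbp_thresh` (strict) lasting at least `min_hypo_min` minutes.
#'
#' @param record A [patient_record()]; must contain an SBP series.
#' @param config A [shock_config()].
#' @return Data frame of episodes (`kind = "hypotension"`).
#' @export
detect_hypotension <- function(record, config = shock_config()) {
  stopifnot(inherits(record, "patient_record"),
            inherits(config, "shock_config"))
  s <- record$series[["SBP"]]
  if (is.null(s) || !length(s$times)) {
    stop("record ", record$patient_id, " has no SBP series", call. = FALSE)
  }
  iv <- hold_intervals(s, function(v) v < config$sbp_thresh,
                       record$icu_stay_h)
  iv <- iv[(iv$end_h - iv$start_h) >= config$min_hypo_min / 60 - .time_eps, ,
           drop = FALSE]
  if (!nrow(iv)) return(empty_episodes())
  episode_frame("hypotension", iv$start_h, iv$end_h)
}

#' Fluid intake in the resuscitation window of a hypotension episode
#'
#' Sums the administered fluid volume over the window running from
#' `fluid_pre_h` hours before the episode start to halfway through the
#' episode, both endpoints included.
#'
#' @param fluids Data frame `time_h`, `volume_ml`.
#' @param hypo_episode One-row episode data frame (or list) with
#'   `start_h`, `end_h`.
#' @param config A [shock_config()].
#' @return Total volume in mL (0 when there are no events in window).
#' @export
fluid_intake_in_window <- function(fluids, hypo_episode,
                                   config = shock_config()) {
  start <- hypo_episode$start_h[1]
  end <- hypo_episode$end_h[1]
  stopifnot(is.finite(start), is.finite(end), end > start)
  lo <- start - config$fluid_pre_h
  hi <- start + (end - start) / 2
  if (!nrow(fluids)) return(0)
  sum(fluids$volume_ml[fluids$time_h >= lo & fluids$time_h <= hi])
}

#' Detect septic shock onset
#'
#' Implements the full rule set. Prolonged hypotension episodes are
#' found; records with none get reason `no_prolonged_hypotension` and
#' records with exactly one are considered without a septic shock
#' episode (reason `single_hypotension_episode`). Otherwise, episodes
#' that temporally overlap a SIRS abnormality episode are eligible, and
#' an eligible episode whose resuscitation-window fluid intake exceeds
#' `fluid_thresh_ml` (strict) is classified as sepsis-induced
#' hypotension. The earliest sepsis-induced episode's start is the
#' shock onset. If the record has no abnormality episode the reason is
#' `no_sirs`; if no eligible episode is fluid-qualified the reason is
#' `no_fluid_qualified`.
#'
#' @param record A [patient_record()].
#' @param sirs A [sirs_config()].
#' @param shock A [shock_config()].
#' @return A list of class `onset_result`: `patient_id`, `onset_h`
#'   (`NA` unless labeled), `reason` (one of `labeled`, `no_sirs`,
#'   `no_prolonged_hypotension`, `single_hypotension_episode`,
#'   `no_fluid_qualified`) and `episodes` (all episodes found, with
#'   sepsis-induced ones marked `kind = "sepsis_induced_hypotension"`
#'   and their window fluid volume in `fluid_ml`).
#' @export
detect_shock_onset <- function(record, sirs = sirs_config(),
                               shock = shock_config()) {
  abn <- detect_abnormality_episodes(record, sirs)
  hypo <- detect_hypotension(record, shock)

  result <- function(onset, reason, episodes) {
    structure(list(patient_id = record$patient_id, onset_h = onset,
                   reason = reason, episodes = episodes),
              class = "onset_result")
  }
  if (nrow(hypo)) {
    hypo$fluid_ml <- vapply(seq_len(nrow(hypo)), function(i) {
      fluid_intake_in_window(record$fluids, hypo[i, ], shock)
    }, 0)
  }
  episodes <- rbind(abn, hypo)
  if (nrow(hypo) == 0L) {
    return(result(NA_real_, "no_prolonged_hypotension", episodes))
  }
  if (nrow(hypo) == 1L) {
    return(result(NA_real_, "single_hypotension_episode", episodes))
  }
  if (nrow(abn) == 0L) {
    return(result(NA_real_, "no_sirs", episodes))
  }
  overlaps_sirs <- vapply(seq_len(nrow(hypo)), function(i) {
    any(abn$start_h < hypo$end_h[i] & abn$end_h > hypo$start_h[i])
  }, TRUE)
  qualified <- overlaps_sirs & hypo$fluid_ml > shock$fluid_thresh_ml
  hypo$kind[qualified] <- "sepsis_induced_hypotension"
  episodes <- rbind(abn, hypo)
  if (!any(qualified)) {
    return(result(NA_real_, "no_fluid_qualified", episodes))
  }
  result(min(hypo$start_h[qualified]), "labeled", episodes)
}

#' Detect onsets for a whole cohort
#'
#' @param records List of [patient_record()].
#' @param sirs,shock Configuration objects.
#' @return List with `onsets` (data frame `patient_id`, `onset_h`,
#'   `reason`) and `episodes` (per-patient episode table).
#' @export
detect_cohort_onsets <- function(records, sirs = sirs_config(),
                                 shock = shock_config()) {
  res <- lapply(records, detect_shock_onset, sirs = sirs, shock = shock)
  onsets <- data.frame(
    patient_id = vapply(res, `[[`, "", "patient_id"),
    onset_h = vapply(res, `[[`, 0, "onset_h"),
    reason = vapply(res, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  episodes <- do.call(rbind, lapply(res, function(r) {
    if (!nrow(r$episodes)) return(NULL)
    cbind(patient_id = r$patient_id, r$episodes, stringsAsFactors = FALSE)
  }))
  if (is.null(episodes)) {
    episodes <- cbind(patient_id = character(), empty_episodes())
  }
  list(onsets = onsets, episodes = episodes)
}
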