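# Synthetic septic-shock cohort generator. Series are piecewise-linear
# baselines plus Gaussian noise with episode-shaped excursions;
# sampling is irregular with exponential inter-arrival times, sparser
# for laboratory variables than for monitored ones. Every generated
# record carries a SIRS-type abnormality period, one decoy prolonged
# hypotension episode whose resuscitation window stays at or below the
# fluid threshold, and one fluid-qualified episode whose start is the
# planted shock onset.

#' Default mean inter-sample intervals (hours)
#'
#' Monitor-derived variables are sampled every 0.25-1 h on average;
#' laboratory variables every 4-12 h, reflecting how often each source
#' is charted in an ICU record.
#'
#' @return Named numeric vector over [VITAL_VARIABLES].
#' @export
default_sampling_rates <- function() {
  c(SBP = 0.5, DBP = 0.5, MAP = 0.5, HR = 0.25, RR = 0.5, CVP = 1,
    CO = 4, T = 2, pH = 8, creatinine = 12, glucose = 6, lactate = 8,
    hematocrit = 12, WBC = 8, SpO2 = 0.5)
}

#' Default survivor/nonsurvivor effect profile
#'
#' Per-variable generation parameters: post-onset baseline level for
#' survivors (`base_S`) and nonsurvivors (`base_NS`), between-patient
#' baseline spread (`base_sd`), post-onset linear trend per group
#' (`slope_S`, `slope_NS`, units/h) with between-patient spread
#' (`slope_sd`), within-series measurement noise per group (`noise_S`,
#' `noise_NS`), and the resting pre-abnormality baseline (`pre`).
#' Group contrasts follow the direction and rough magnitude of
#' published survivor/nonsurvivor comparisons in septic shock:
#' nonsurvivors run lower blood pressures with negative pressure and
#' SpO2 trends, higher lactate and central venous pressure, lower pH
#' and cardiac output, and higher heart and respiratory rates.
#'
#' @return Data frame with one row per variable.
#' @export
default_effect_profile <- function() {
  tab <- rbind(
    #            base_S  base_NS base_sd slope_S slope_NS slope_sd noise_S noise_NS   pre
    SBP        = c(100,    91,     5,    0.33,   -0.04,    0.10,    4,      4,      115),
    DBP        = c(59,     52,     4,    0.14,   -0.13,    0.12,    3,      3,       65),
    MAP        = c(75,     64,     5,    0.23,   -0.15,    0.15,    3,      3,       82),
    HR         = c(103,    115,    8,    0,       0,       0.05,    5,      5,       80),
    RR         = c(23,     25,     2,    0,       0,       0.02,    1.5,    1.5,     16),
    CVP        = c(14.3,   17.3,   1.5,  0,       0,       0.02,    2,      2,       10),
    CO         = c(6.5,    5.2,    1.0,  0,       0,       0.01,    0.7,    0.7,     5.5),
    T          = c(38.4,   38.7,   0.3,  0,       0,       0.002,   0.25,   0.25,    36.9),
    pH         = c(7.32,   7.21,   0.05, 0.002,  -0.001,   0.001,   0.03,   0.03,    7.38),
    creatinine = c(1.4,    1.8,    0.5,  0,       0.002,   0.002,   0.15,   0.15,    1.2),
    glucose    = c(140,    150,    25,   0,       0,       0.05,    15,     15,      120),
    lactate    = c(3.2,    6.7,    1.2,  -0.01,   0.02,    0.01,    0.6,    0.6,     1.5),
    hematocrit = c(30,     29,     3,    0,       0,       0.01,    1.5,    1.5,     32),
    WBC        = c(16000,  17500,  2500, 0,       0,       5,       3000,   5000,    8000),
    SpO2       = c(97.3,   94.4,   1.0,  0,      -0.19,    0.04,    1.2,    1.2,     97.5))
  colnames(tab) <- c("base_S", "base_NS", "base_sd", "slope_S",
                     "slope_NS", "slope_sd", "noise_S", "noise_NS",
                     "pre")
  as.data.frame(tab)
}

#' Default shock-episode generation profile
#'
#' Controls the planted hypotension structure: the abnormality period
#' start, the decoy episode (non-fluid-qualified) and onset episode
#' (fluid-qualified) durations, the gap separating them, bolus and
#' decoy fluid volume ranges, and background maintenance fluids. All
#' ranges are `c(min, max)` of a uniform draw.
#'
#' @return Named list.
#' @export
default_shock_profile <- function() {
  list(abn_start_h = c(2, 5),
       decoy_delay_h = c(2, 4),     # after abnormality start
       decoy_dur_h = c(0.75, 1.5),
       decoy_fluid_ml = c(100, 400),
       onset_gap_h = c(3, 5),       # after decoy end
       onset_dur_h = c(1.5, 3),
       bolus_ml = c(650, 1200),
       dip_sbp = c(72, 82),
       maintenance_ml = 80,
       maintenance_every_h = 4,
       survivor_extra_stay_h = c(24, 96),
       ns_death_after_onset_h = c(50, 160))
}

#' Minimal effect profile planting exactly five informative features
#'
#' Like [default_effect_profile()] but with every survivor/nonsurvivor
#' contrast removed except the five planted ones (mean MAP, mean SpO2,
#' mean lactate, mean CVP, SBP slope), whose standardized group
#' differences are about 2 or larger. Useful when an experiment needs
#' the ground truth "informative feature" set to be exactly the
#' planted list rather than the broad multi-variable contrast pattern
#' seen in real septic-shock cohorts.
#'
#' @return Data frame with one row per variable.
#' @export
minimal_effect_profile <- function() {
  ep <- default_effect_profile()
  ep$base_NS <- ep$base_S
  ep$slope_NS <- ep$slope_S
  ep$noise_NS <- ep$noise_S
  ep["MAP", "base_NS"] <- 64
  ep["MAP", "slope_NS"] <- ep["MAP", "slope_S"] # level effect only
  ep["SpO2", "base_NS"] <- 94.4
  ep["lactate", "base_NS"] <- 6.7
  ep["CVP", "base_NS"] <- 17.3
  ep["SBP", "slope_NS"] <- -0.04 # trend effect only
  ep
}

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of patients (>= 2).
#' @param nonsurvivor_fraction Fraction labeled nonsurvivor; the
#'   realized count is `round(n_patients * nonsurvivor_fraction)`.
#' @param sampling_rates Named mean inter-sample intervals (hours),
#'   see [default_sampling_rates()].
#' @param effect_profile See [default_effect_profile()].
#' @param shock_profile See [default_shock_profile()].
#' @param seed Integer seed; generation is a deterministic function of
#'   the spec including this seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 73L, nonsurvivor_fraction = 20 / 73,
                        sampling_rates = default_sampling_rates(),
                        effect_profile = default_effect_profile(),
                        shock_profile = default_shock_profile(),
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L) {
    stop("n_patients must be an integer >= 2", call. = FALSE)
  }
  stopifnot(nonsurvivor_fraction >= 0, nonsurvivor_fraction <= 1)
  if (!all(VITAL_VARIABLES %in% names(sampling_rates)) ||
      any(sampling_rates[VITAL_VARIABLES] <= 0)) {
    stop("sampling_rates must give a positive mean interval for all 15 ",
         "variables", call. = FALSE)
  }
  stopifnot(all(rownames(effect_profile) == VITAL_VARIABLES))
  sp <- shock_profile
  if (sp$onset_gap_h[1] < 1.5) {
    stop("infeasible shock profile: onset_gap_h must allow >= 1.5 h ",
         "between decoy and onset episodes", call. = FALSE)
  }
  structure(list(n_patients = n_patients,
                 nonsurvivor_fraction = nonsurvivor_fraction,
                 sampling_rates = sampling_rates[VITAL_VARIABLES],
                 effect_profile = effect_profile,
                 shock_profile = sp,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Features the default generator plants as group-informative
#'
#' The five indexes whose survivor/nonsurvivor standardized difference
#' under [default_effect_profile()] is large (>= about 2): mean MAP,
#' mean SpO2, mean lactate, mean CVP and SBP slope.
#'
#' @return Character vector of 5 feature names.
#' @export
planted_feature_names <- function() {
  c("mean_MAP", "mean_SpO2", "mean_lactate", "mean_CVP", "slope_SBP")
}

runif1 <- function(range) runif(1, range[1], range[2])

sample_times <- function(stay, mean_gap) {
  n_draw <- ceiling(stay / mean_gap * 1.6) + 25L
  t <- cumsum(c(runif(1, 0, mean_gap), rexp(n_draw, 1 / mean_gap)))
  while (t[length(t)] <= stay) { # rare under-draw
    t <- c(t, t[length(t)] + cumsum(rexp(n_draw, 1 / mean_gap)))
  }
  t[t <= stay]
}

clamp_var <- function(v, values) {
  switch(v,
         SpO2 = pmin(values, 100),
         lactate = pmax(values, 0.3),
         WBC = pmax(values, 500),
         CO = pmax(values, 0.5),
         creatinine = pmax(values, 0.2),
         values)
}

generate_patient <- function(pid, group, spec, with_effects) {
  ep <- spec$effect_profile
  sp <- spec$shock_profile
  g <- if (with_effects) group else "S"

  abn_start <- runif1(sp$abn_start_h)
  decoy_start <- abn_start + runif1(sp$decoy_delay_h)
  decoy_end <- decoy_start + runif1(sp$decoy_dur_h)
  onset <- decoy_end + runif1(sp$onset_gap_h)
  onset_dur <- runif1(sp$onset_dur_h)

  if (group == "NS") {
    death_offset <- runif1(sp$ns_death_after_onset_h)
    stay <- onset + death_offset
    death <- onset + death_offset
  } else {
    stay <- onset + 48 + runif1(sp$survivor_extra_stay_h)
    death <- NA_real_
  }

  base_col <- paste0("base_", g)
  slope_col <- paste0("slope_", g)
  noise_col <- paste0("noise_", g)

  series <- list()
  for (v in VITAL_VARIABLES) {
    tt <- sample_times(stay, spec$sampling_rates[[v]])
    if (v == "SBP") {
      # pin samples at the planted episode boundaries so the held
      # intervals start exactly where the ground truth says
      tt <- c(tt, decoy_start, decoy_end, onset, onset + onset_dur)
      tt <- sort(tt[tt <= stay])
      tt <- tt[!duplicated(round(tt, 9))]
    }
    if (!length(tt)) next
    p <- ep[v, ]
    base_i <- p[[base_col]] + rnorm(1, 0, p$base_sd)
    slope_i <- p[[slope_col]] + rnorm(1, 0, p$slope_sd)
    noise <- rnorm(length(tt), 0, p[[noise_col]])

    # abnormality-period shaping: HR/RR/T/WBC move to the septic
    # baseline from abn_start on (T returns to normal late in the stay)
    post <- switch(v,
                   HR = , RR = , WBC = tt >= abn_start,
                   T = tt >= abn_start & tt <= abn_start + 40,
                   tt >= onset)
    baseline <- ifelse(post, base_i + slope_i * pmax(tt - onset, 0),
                       p$pre)
    vals <- baseline + noise
    if (v == "SBP") {
      in_decoy <- tt >= decoy_start & tt < decoy_end
      in_onset <- tt >= onset & tt < onset + onset_dur
      dip <- runif1(sp$dip_sbp)
      vals[in_decoy] <- pmin(dip + rnorm(sum(in_decoy), 0, 2), 86)
      vals[in_onset] <- pmin(dip - 3 + rnorm(sum(in_onset), 0, 2), 86)
      # keep pre-onset non-dip SBP safely normotensive
      pre_sbp <- tt < onset & !in_decoy
      vals[pre_sbp] <- pmax(vals[pre_sbp], 95)
    }
    vals <- clamp_var(v, vals)
    series[[v]] <- vital_series(v, tt, round(vals, 6))
  }

  # fluids: maintenance drip events plus the decoy volume and the
  # qualifying bolus just after onset
  mt <- seq(sp$maintenance_every_h / 2, stay, by = sp$maintenance_every_h)
  fluids <- data.frame(time_h = mt,
                       volume_ml = rep(sp$maintenance_ml, length(mt)))
  fluids <- rbind(fluids,
                  data.frame(time_h = decoy_start + 0.1,
                             volume_ml = runif1(sp$decoy_fluid_ml)),
                  data.frame(time_h = onset + 0.05,
                             volume_ml = runif1(sp$bolus_ml)))
  fluids <- fluids[order(fluids$time_h), ]

  rec <- patient_record(pid, series, fluids, icu_stay_h = stay,
                        death_time_h = death,
                        age_years = runif(1, 25, 90))
  list(record = rec, true_onset_h = onset, label = group)
}

generate_cohort_impl <- function(spec, with_effects) {
  stopifnot(inherits(spec, "cohort_spec"))
  run_rng(spec$seed, {
    n <- spec$n_patients
    n_ns <- round(n * spec$nonsurvivor_fraction)
    ids <- sprintf("p%03d", seq_len(n))
    ns_idx <- sample(n, n_ns)
    labels <- ifelse(seq_len(n) %in% ns_idx, "NS", "S")
    pats <- lapply(seq_len(n), function(i) {
      generate_patient(ids[i], labels[i], spec, with_effects)
    })
    truth <- data.frame(
      patient_id = ids,
      true_onset_h = vapply(pats, `[[`, 0, "true_onset_h"),
      label = labels, stringsAsFactors = FALSE)
    list(records = lapply(pats, `[[`, "record"),
         truth = structure(list(truth = truth,
                                planted_features = if (with_effects)
                                  planted_feature_names() else character()),
                           class = "ground_truth"))
  })
}

#' Generate a synthetic septic-shock cohort
#'
#' Produces records that pass the inclusion criteria and contain, by
#' construction, a SIRS abnormality period, one decoy prolonged
#' hypotension episode whose window fluid stays at or below the
#' threshold and one fluid-qualified episode whose start is the ground
#' truth shock onset. Survivor/nonsurvivor differences are planted per
#' the effect profile; nonsurvivors die within 7 days of onset.
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (patient records) and `truth` (a
#'   `ground_truth`: per-patient `true_onset_h` and `label`, plus the
#'   planted feature names).
#' @export
generate_cohort <- function(spec) {
  generate_cohort_impl(spec, with_effects = TRUE)
}

#' Generate a null cohort (labels independent of all series)
#'
#' Identical generation machinery, but all patients are drawn from the
#' survivor physiology and the survivor/nonsurvivor labels (with their
#' consistent death times) are assigned independently of the series,
#' so any feature flagged as group-different is a false discovery.
#'
#' @param spec A [cohort_spec()].
#' @return As [generate_cohort()]; `planted_features` is empty.
#' @export
generate_null_cohort <- function(spec) {
  generate_cohort_impl(spec, with_effects = FALSE)
}
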