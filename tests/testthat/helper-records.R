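# Builders for small hand-constructed patient records.

make_series <- function(variable, times, values) {
  vital_series(variable, times, values)
}

# series_spec: named list variable -> list(times, values)
make_record <- function(series_spec, stay = 48, fluids = NULL,
                        death = NA_real_, id = "toy") {
  series <- lapply(names(series_spec), function(v) {
    s <- series_spec[[v]]
    vital_series(v, s[[1]], s[[2]])
  })
  names(series) <- names(series_spec)
  if (is.null(fluids)) {
    fluids <- data.frame(time_h = numeric(), volume_ml = numeric())
  }
  patient_record(id, series, fluids, icu_stay_h = stay,
                 death_time_h = death, age_years = 60)
}

# the worked abnormality example: temperature > 38 held over hours
# 1-23, first abnormal WBC measured at hour 6; expected episode start 1
worked_example_record <- function() {
  make_record(list(
    T = list(c(0, 1:23, 24), c(37, rep(38.5, 23), 37)),
    WBC = list(c(6, 26), c(15000, 9000)),
    HR = list(0, 80),
    RR = list(0, 15),
    SBP = list(0, 120)),
    stay = 48)
}

# random record with all sample times on the 1-minute grid, for
# comparison against the brute-force minute-scan oracle
random_minute_record <- function(seed) {
  set.seed(seed)
  stay_min <- sample(1440:4320, 1)
  stay <- stay_min / 60
  draw <- function(v, gen) {
    n <- sample(3:40, 1)
    t <- sort(sample(0:(stay_min - 1), n)) / 60
    vital_series(v, t, gen(n))
  }
  series <- list(
    T = draw("T", function(n) rnorm(n, 37.5, 1.5)),
    HR = draw("HR", function(n) rnorm(n, 90, 15)),
    RR = draw("RR", function(n) rnorm(n, 20, 4)),
    WBC = draw("WBC", function(n) runif(n, 2000, 16000)),
    SBP = draw("SBP", function(n) rnorm(n, 92, 10)))
  nf <- sample(0:8, 1)
  fluids <- data.frame(time_h = sort(sample(0:stay_min, nf)) / 60,
                       volume_ml = runif(nf, 0, 500))
  patient_record(paste0("rnd", seed), series, fluids,
                 icu_stay_h = stay, age_years = 50)
}

# minimal cohort_matrix for model-level tests that do not need the
# feature-extraction machinery
make_matrix <- function(x, labels) {
  colnames(x) <- if (is.null(colnames(x)))
    paste0("f", seq_len(ncol(x))) else colnames(x)
  structure(list(x = x, feature_names = colnames(x),
                 patient_ids = paste0("p", seq_len(nrow(x))),
                 labels = factor(labels, levels = c("S", "NS")),
                 missing_mask = matrix(FALSE, nrow(x), ncol(x)),
                 imputed_means = colMeans(x)),
            class = "cohort_matrix")
}
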