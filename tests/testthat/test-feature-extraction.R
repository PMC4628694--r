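test_that("window restriction keeps closed endpoints and re-times", {
  rec <- make_record(list(
    HR = list(c(5, 12, 58, 60), c(70, 80, 90, 95)),
    SBP = list(c(60, 70), c(120, 110))),
    stay = 80)
  win <- window_series(rec, onset_h = 10, width_h = 48)
  expect_equal(win$HR$times, c(2, 48)) # 12 and 58, re-timed
  expect_equal(win$HR$values, c(80, 90))
  expect_null(win$CO)
  # sample exactly at onset + 48 retained (closed endpoint)
  expect_true(48 %in% win$HR$times)
  # variable with no samples in window absent from the result
  win2 <- window_series(rec, onset_h = 0, width_h = 48)
  expect_false("SBP" %in% names(win2))
})

test_that("summary statistics match closed forms", {
  s <- make_series("HR", c(0, 1, 2), c(1, 2, 3))
  st <- summarize_series(s)
  expect_equal(st[["mean"]], 2)
  expect_equal(st[["std"]], 1)
  expect_equal(st[["min"]], 1)
  expect_equal(st[["max"]], 3)
  expect_equal(st[["median"]], 2)
  expect_equal(st[["slope"]], 1)
  expect_equal(st[["delta"]], 2)
  expect_equal(st[["skewness"]], 0)
  expect_true(is.na(st[["kurtosis"]])) # needs n >= 4

  # closed-form check on an asymmetric 4-point series
  v <- c(1, 1, 2, 6); t <- c(0, 2, 3, 7)
  st <- summarize_series(make_series("HR", t, v))
  m <- mean(v)
  expect_equal(st[["skewness"]], mean((v - m)^3) / mean((v - m)^2)^1.5)
  expect_equal(st[["kurtosis"]], mean((v - m)^4) / mean((v - m)^2)^2)
  expect_equal(st[["slope"]],
               sum((t - mean(t)) * (v - m)) / sum((t - mean(t))^2))
})

test_that("constant series use the zero-variance conventions", {
  st <- summarize_series(make_series("HR", 0:3, rep(5, 4)))
  expect_equal(st[["std"]], 0)
  expect_equal(st[["slope"]], 0)
  expect_equal(st[["delta"]], 0)
  expect_true(is.na(st[["skewness"]]))
  expect_true(is.na(st[["kurtosis"]]))
})

test_that("minimum sample counts gate each statistic", {
  st1 <- summarize_series(make_series("HR", 1, 7))
  expect_equal(st1[["mean"]], 7)
  expect_true(all(is.na(st1[c("std", "slope", "delta",
                              "skewness", "kurtosis")])))
  st2 <- summarize_series(make_series("HR", c(1, 2), c(7, 9)))
  expect_equal(st2[["delta"]], 2)
  expect_true(is.na(st2[["skewness"]]))
  st3 <- summarize_series(make_series("HR", 1:3, c(7, 9, 8)))
  expect_false(is.na(st3[["skewness"]]))
  expect_true(is.na(st3[["kurtosis"]]))
})

test_that("Pearson kurtosis of a large Gaussian sample approaches 3", {
  set.seed(42)
  st <- summarize_series(make_series("HR", seq_len(1e5) / 1000,
                                     rnorm(1e5)))
  expect_equal(st[["kurtosis"]], 3, tolerance = 0.2 / 3)
})

test_that("shift/scale equivariance and time-shift invariance hold", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    t <- sort(runif(n, 0, 48))
    v <- rnorm(n, 50, 8)
    base <- summarize_series(make_series("HR", t, v))
    shifted <- summarize_series(make_series("HR", t, v + 13))
    expect_equal(shifted[["mean"]], base[["mean"]] + 13)
    expect_equal(shifted[["median"]], base[["median"]] + 13)
    expect_equal(shifted[["min"]], base[["min"]] + 13)
    expect_equal(shifted[["max"]], base[["max"]] + 13)
    for (s in c("std", "skewness", "kurtosis", "slope", "delta")) {
      expect_equal(shifted[[s]], base[[s]])
    }
    scaled <- summarize_series(make_series("HR", t, v * 2.5))
    for (s in c("mean", "std", "min", "max", "median", "slope", "delta")) {
      expect_equal(scaled[[s]], base[[s]] * 2.5)
    }
    expect_equal(scaled[["skewness"]], base[["skewness"]])
    expect_equal(scaled[["kurtosis"]], base[["kurtosis"]])
    retimed <- summarize_series(make_series("HR", t - t[1], v))
    expect_equal(retimed, base)
  }
})

test_that("feature vectors always carry the 135 canonical keys", {
  expect_length(feature_names(), 135)
  expect_false(anyDuplicated(feature_names()) > 0)

  gen <- generate_cohort(cohort_spec(n_patients = 2, seed = 3))
  rec <- gen$records[[1]]
  fv <- extract_features(rec, gen$truth$truth$true_onset_h[1])
  expect_identical(names(fv$values), feature_names())

  # dropping a whole variable leaves its 9 features missing
  rec2 <- rec
  rec2$series$CO <- NULL
  fv2 <- extract_features(rec2, gen$truth$truth$true_onset_h[1])
  co_feats <- paste0(FEATURE_STATS, "_CO")
  expect_true(all(is.na(fv2$values[co_feats])))
  expect_identical(names(fv2$values), feature_names())
})

test_that("the 7-day label boundary is inclusive at 168 h", {
  base <- list(HR = list(c(0, 1), c(80, 82)))
  rec_ns <- make_record(base, stay = 300, death = 10 + 167)
  expect_identical(extract_features(rec_ns, 10)$label, "NS")
  rec_168 <- make_record(base, stay = 300, death = 10 + 168)
  expect_identical(extract_features(rec_168, 10)$label, "NS")
  rec_s <- make_record(base, stay = 300, death = 10 + 169)
  expect_identical(extract_features(rec_s, 10)$label, "S")
  rec_alive <- make_record(base, stay = 300)
  expect_identical(extract_features(rec_alive, 10)$label, "S")
})

test_that("mean imputation fills gaps without moving column means", {
  fv <- function(id, vals, label) {
    v <- setNames(rep(1, 135), feature_names())
    v[names(vals)] <- vals
    structure(list(patient_id = id, values = v, label = label),
              class = "feature_vector")
  }
  a <- fv("a", c(mean_HR = 1), "S")
  b <- fv("b", c(mean_HR = NA_real_), "NS")
  c3 <- fv("c", c(mean_HR = 3), "S")
  cm <- assemble_matrix(list(a, b, c3))
  expect_equal(unname(cm$x[, "mean_HR"]), c(1, 2, 3))
  expect_true(cm$missing_mask[2, "mean_HR"])
  expect_equal(sum(cm$missing_mask), 1)
  expect_equal(cm$imputed_means[["mean_HR"]], 2)

  # property: random masks keep observed column means; variance shrinks
  set.seed(9)
  for (i in 1:5) {
    x <- matrix(rnorm(20 * 135), 20, 135)
    colnames(x) <- feature_names()
    mask <- matrix(runif(20 * 135) < 0.2, 20, 135)
    mask[1, ] <- FALSE # keep every feature observed at least once
    xm <- x; xm[mask] <- NA
    fvs <- lapply(1:20, function(r) {
      structure(list(patient_id = paste0("p", r),
                     values = setNames(xm[r, ], feature_names()),
                     label = if (r <= 10) "S" else "NS"),
                class = "feature_vector")
    })
    cm <- assemble_matrix(fvs)
    obs_means <- colMeans(xm, na.rm = TRUE)
    expect_equal(unname(colMeans(cm$x)), unname(obs_means))
    v_obs <- apply(xm, 2, var, na.rm = TRUE)
    v_imp <- apply(cm$x, 2, var)
    expect_true(all(v_imp <= v_obs + 1e-12))
  }
})

test_that("a feature observed for no patient is an error", {
  v1 <- setNames(rep(1, 135), feature_names())
  v2 <- v1
  v1["kurtosis_CO"] <- NA
  v2["kurtosis_CO"] <- NA
  fvs <- list(
    structure(list(patient_id = "a", values = v1, label = "S"),
              class = "feature_vector"),
    structure(list(patient_id = "b", values = v2, label = "NS"),
              class = "feature_vector"))
  expect_error(assemble_matrix(fvs), "kurtosis_CO")
})
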