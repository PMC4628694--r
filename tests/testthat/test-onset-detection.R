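test_that("hold intervals follow sample-and-hold semantics", {
  s <- make_series("HR", c(0, 3, 5), c(95, 80, 100))
  iv <- hold_intervals(s, function(v) v > 90, end_h = 8)
  expect_equal(iv$start_h, c(0, 5))
  expect_equal(iv$end_h, c(3, 8))

  iv <- hold_intervals(make_series("HR", c(1, 2), c(95, 96)),
                       function(v) v > 90, end_h = 10)
  expect_equal(iv, data.frame(start_h = 1, end_h = 10))

  iv <- hold_intervals(make_series("HR", c(1, 2), c(80, 85)),
                       function(v) v > 90, end_h = 10)
  expect_equal(nrow(iv), 0)
})

test_that("abnormality episode start backtracks to the first abnormal
           measurement", {
  ep <- detect_abnormality_episodes(worked_example_record())
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_h, 1)
  expect_equal(ep$end_h, 24)
  expect_match(ep$contributing, "temperature")
  expect_match(ep$contributing, "wbc")
})

test_that("abnormal intervals under 6 h apart merge into one episode", {
  # HR and RR simultaneously abnormal on [0, 5.5] and [9, 15]
  rec <- make_record(list(
    HR = list(c(0, 5.5, 9, 15), c(110, 80, 120, 82)),
    RR = list(c(0, 5.5, 9, 15), c(25, 14, 30, 15))),
    stay = 20)
  ep <- detect_abnormality_episodes(rec)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_h, 0)
  expect_equal(ep$end_h, 15)
})

test_that("episodes lasting 5 h or less are discarded", {
  rec <- make_record(list(
    HR = list(c(0, 4), c(110, 80)),
    RR = list(c(0, 4), c(25, 14))),
    stay = 20)
  expect_equal(nrow(detect_abnormality_episodes(rec)), 0)
  # an exactly 5 h episode is still discarded (strictly more than 5 h)
  rec5 <- make_record(list(
    HR = list(c(0, 5), c(110, 80)),
    RR = list(c(0, 5), c(25, 14))),
    stay = 20)
  expect_equal(nrow(detect_abnormality_episodes(rec5)), 0)
  rec6 <- make_record(list(
    HR = list(c(0, 6), c(110, 80)),
    RR = list(c(0, 6), c(25, 14))),
    stay = 20)
  expect_equal(nrow(detect_abnormality_episodes(rec6)), 1)
})

test_that("min_criteria = 4 requires all four criteria at once", {
  rec <- make_record(list(
    HR = list(0, 110), RR = list(0, 25),
    T = list(0, 39), WBC = list(c(0, 10), c(15000, 8000))),
    stay = 20)
  ep2 <- detect_abnormality_episodes(rec, sirs_config(min_criteria = 2))
  ep4 <- detect_abnormality_episodes(rec, sirs_config(min_criteria = 4))
  expect_equal(ep2$end_h, 20)
  expect_equal(ep4$end_h, 10) # ends when WBC normalizes
})

test_that("hypotension episodes need 30 held minutes below 90", {
  rec <- make_record(list(SBP = list(c(10, 10.4), c(85, 120))), stay = 20)
  expect_equal(nrow(detect_hypotension(rec)), 0) # 24 min
  rec <- make_record(list(SBP = list(c(10, 14), c(85, 120))), stay = 20)
  hy <- detect_hypotension(rec)
  expect_equal(hy[, c("start_h", "end_h")],
               data.frame(start_h = 10, end_h = 14))
  # exactly 30 minutes qualifies
  rec <- make_record(list(SBP = list(c(10, 10.5), c(85, 120))), stay = 20)
  expect_equal(nrow(detect_hypotension(rec)), 1)
  # boundary: SBP exactly 90 is not hypotension
  rec <- make_record(list(SBP = list(c(0, 5), c(90, 90))), stay = 20)
  expect_equal(nrow(detect_hypotension(rec)), 0)
  # no SBP series is an error
  expect_error(detect_hypotension(make_record(list(HR = list(0, 80)),
                                              stay = 20)), "SBP")
})

test_that("fluid window spans one hour before start to episode midpoint,
           closed at both ends", {
  ep <- data.frame(start_h = 10, end_h = 14)
  fl <- data.frame(time_h = c(9.5, 11, 13), volume_ml = c(500, 300, 400))
  expect_equal(fluid_intake_in_window(fl, ep), 800) # window [9, 12]
  expect_equal(fluid_intake_in_window(fl[0, ], ep), 0)
  expect_equal(fluid_intake_in_window(
    data.frame(time_h = c(9, 12), volume_ml = c(100, 50)), ep), 150)
})

test_that("shock onset labeling follows the episode-count and fluid rules", {
  sirs_series <- list(HR = list(0, 110), RR = list(0, 25))
  # two hypotension episodes inside the SIRS period, first qualified
  rec <- make_record(c(sirs_series, list(
    SBP = list(c(8, 10, 14, 16.5), c(85, 120, 85, 120)))),
    stay = 30,
    fluids = data.frame(time_h = c(7.5, 13.9), volume_ml = c(700, 500)))
  res <- detect_shock_onset(rec)
  expect_identical(res$reason, "labeled")
  expect_equal(res$onset_h, 8)
  expect_true("sepsis_induced_hypotension" %in% res$episodes$kind)

  # one hypotensive episode only: record without septic shock
  rec1 <- make_record(c(sirs_series, list(
    SBP = list(c(8, 10), c(85, 120)))),
    stay = 30,
    fluids = data.frame(time_h = 7.5, volume_ml = 1200))
  res1 <- detect_shock_onset(rec1)
  expect_identical(res1$reason, "single_hypotension_episode")
  expect_true(is.na(res1$onset_h))

  # intakes of exactly 600 mL do not qualify (strictly larger than 600)
  rec2 <- make_record(c(sirs_series, list(
    SBP = list(c(8, 10, 14, 16.5), c(85, 120, 85, 120)))),
    stay = 30,
    fluids = data.frame(time_h = c(7.5, 13.9), volume_ml = c(600, 600)))
  res2 <- detect_shock_onset(rec2)
  expect_identical(res2$reason, "no_fluid_qualified")

  # no SIRS episode at all
  rec3 <- make_record(list(
    HR = list(0, 70), RR = list(0, 14),
    SBP = list(c(8, 10, 14, 16.5), c(85, 120, 85, 120))),
    stay = 30,
    fluids = data.frame(time_h = 7.5, volume_ml = 1200))
  expect_identical(detect_shock_onset(rec3)$reason, "no_sirs")
})

test_that("hypotension intervals are monotone in the SBP threshold", {
  set.seed(21)
  for (i in 1:10) {
    rec <- random_minute_record(100 + i)
    lo <- detect_hypotension(rec, shock_config(sbp_thresh = 80,
                                               min_hypo_min = 1e-6))
    hi <- detect_hypotension(rec, shock_config(sbp_thresh = 95,
                                               min_hypo_min = 1e-6))
    if (nrow(lo)) {
      for (k in seq_len(nrow(lo))) {
        expect_true(any(hi$start_h <= lo$start_h[k] &
                        hi$end_h >= lo$end_h[k]))
      }
    }
  }
})

test_that("episode detection matches the minute-grid oracle on random
           records", {
  sirs <- sirs_config(); shock <- shock_config()
  for (seed in 1:25) {
    rec <- random_minute_record(seed)
    abn <- detect_abnormality_episodes(rec, sirs)
    oa <- oracle_abnormality(rec, sirs)
    expect_equal(abn$start_h, oa$start_h, tolerance = 1e-9,
                 info = paste("abn start, seed", seed))
    expect_equal(abn$end_h, oa$end_h, tolerance = 1e-9,
                 info = paste("abn end, seed", seed))
    hy <- detect_hypotension(rec, shock)
    oh <- oracle_hypotension(rec, shock)
    expect_equal(hy$start_h, oh$start_h, tolerance = 1e-9,
                 info = paste("hypo start, seed", seed))
    expect_equal(hy$end_h, oh$end_h, tolerance = 1e-9,
                 info = paste("hypo end, seed", seed))
    res <- detect_shock_onset(rec, sirs, shock)
    ores <- oracle_onset(rec, sirs, shock)
    expect_identical(res$reason, ores$reason,
                     info = paste("reason, seed", seed))
    expect_equal(res$onset_h, ores$onset_h, tolerance = 1e-9,
                 info = paste("onset, seed", seed))
  }
})

test_that("merging is idempotent and detection deterministic", {
  rec <- random_minute_record(999)
  a <- detect_abnormality_episodes(rec)
  b <- detect_abnormality_episodes(rec)
  expect_identical(a, b)
  if (nrow(a) > 0) {
    # re-running the merge on its own output changes nothing
    m <- shockwatch:::merge_gapped(a$start_h, a$end_h, 6)
    expect_equal(m$start, a$start_h)
    expect_equal(m$end, a$end_h)
  }
  r1 <- detect_shock_onset(rec)
  r2 <- detect_shock_onset(rec)
  expect_identical(r1, r2)
})
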