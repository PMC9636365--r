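test_that("rolling-window peak finds the best contiguous window", {
  r <- rolling_window_peak(c(100, 110, 120, 130, 120, 110), window = 3)
  expect_equal(r$value, mean(c(120, 130, 120)))
  expect_equal(r$start_time, 2)

  # constant signal: peak equals the constant for any window
  expect_equal(rolling_window_peak(rep(7.5, 50), 30)$value, 7.5)

  # window longer than the series is a precondition violation
  expect_error(rolling_window_peak(1:5, 10), "shorter")
})

test_that("rolling-window peak agrees with the exhaustive scan", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(30:300, 1)
    x <- rnorm(n, 150, 20)
    w <- sample(2:min(n, 120), 1)
    got <- rolling_window_peak(x, w)
    want <- oracle_rolling_peak(x, w)
    expect_equal(got$value, want$value)
    expect_equal(got$start_time, want$start - 1)  # 0-based time grid
  }
})

test_that("full-length window equals the overall mean, and peak >= mean", {
  set.seed(3)
  x <- rnorm(100, 3, 1)
  expect_equal(rolling_window_peak(x, 100)$value, mean(x))
  for (w in c(5, 20, 60))
    expect_gte(rolling_window_peak(x, w)$value, mean(x))
})

test_that("heart-rate recovery is peak 30-s mean minus recovery heart rate", {
  # bout at constant 180 bpm, recovery at constant 150 bpm
  hr <- c(rep(180, 120), rep(150, 200))
  series <- data.frame(time_s = seq_along(hr) - 1, hr_bpm = hr)
  bouts <- data.frame(start_s = 0, end_s = 119)
  res <- heart_rate_recovery(series, bouts, timepoints = c(30, 60))
  expect_equal(res$per_bout$hrr_30, 30)
  expect_equal(res$per_bout$hrr_60, 30)

  # constant trace throughout: HRR is zero at every timepoint
  flat <- data.frame(time_s = 0:299, hr_bpm = 160)
  r0 <- heart_rate_recovery(flat, bouts, timepoints = c(30, 60))
  expect_equal(unname(r0$session_mean), c(0, 0))

  # truncated recovery: timepoint beyond the trace is missing
  short <- data.frame(time_s = 0:130, hr_bpm = hr[1:131])
  rt <- heart_rate_recovery(short, bouts, timepoints = c(5, 60))
  expect_false(is.na(rt$per_bout$hrr_5))
  expect_true(is.na(rt$per_bout$hrr_60))
})

test_that("per-interval HRR values average into a session mean", {
  hr <- c(rep(180, 60), rep(160, 60),  # bout 1 + recovery (HRR30 = 20)
          rep(190, 60), rep(160, 60))  # bout 2 + recovery (HRR30 = 30)
  series <- data.frame(time_s = seq_along(hr) - 1, hr_bpm = hr)
  bouts <- data.frame(start_s = c(0, 120), end_s = c(59, 179))
  res <- heart_rate_recovery(series, bouts, timepoints = 30)
  expect_equal(res$per_bout$hrr_30, c(20, 30))
  expect_equal(unname(res$session_mean["hrr_30"]), 25)
})

test_that("HRR is non-decreasing along a non-increasing recovery trace", {
  hr <- c(rep(185, 60), 185 - cumsum(runif(120, 0, 1)))
  series <- data.frame(time_s = seq_along(hr) - 1, hr_bpm = hr)
  res <- heart_rate_recovery(series, data.frame(start_s = 0, end_s = 59),
                             timepoints = c(10, 30, 60, 90))
  vals <- unname(unlist(res$per_bout[paste0("hrr_", c(10, 30, 60, 90))]))
  expect_true(all(diff(vals) >= 0))
})

test_that("Brouwer stoichiometry pins the substrate extremes", {
  # RER 1.0: essentially pure carbohydrate oxidation
  r1 <- brouwer_substrates(2.0, 2.0)
  expect_equal(r1$cho_gmin, 2.41)
  expect_equal(r1$fat_raw, -0.012)
  expect_equal(r1$fat_gmin, 0)
  expect_false(r1$rer_out_of_range)

  # RER 0.7: essentially pure fat oxidation
  r2 <- brouwer_substrates(2.0, 1.4)
  expect_equal(r2$fat_gmin, 1.0086)
  expect_equal(r2$cho_raw, -0.092)
  expect_equal(r2$cho_gmin, 0)

  # VCO2 = 0 is physiologically impossible: flagged, clipped
  r3 <- brouwer_substrates(2.0, 0)
  expect_equal(r3$fat_gmin, 3.39)
  expect_equal(r3$cho_gmin, 0)
  expect_true(r3$rer_out_of_range)

  expect_error(brouwer_substrates(0, 1), "vo2")
})

test_that("oxidation rates increase in their driving gas within RER 0.7-1.0", {
  vo2 <- 3.0
  vco2 <- seq(0.7, 1.0, by = 0.05) * vo2
  r <- brouwer_substrates(vo2, vco2)
  expect_true(all(diff(r$cho_raw) > 0))   # cho rises with VCO2
  expect_true(all(diff(r$fat_raw) < 0))   # fat falls as RER rises
  vo2s <- seq(2, 4, by = 0.25)
  r2 <- brouwer_substrates(vo2s, 0.8 * vo2s[1])
  expect_true(all(diff(r2$fat_raw) > 0))  # fat rises with VO2 at fixed VCO2
})

test_that("efficiency and exertion ratios are guarded against bad denominators", {
  r <- efficiency_ratios(power_w = 250, hr_bpm = 178)
  expect_equal(r$w_per_hr, 250 / 178, tolerance = 1e-12)
  expect_equal(round(r$w_per_hr, 3), 1.404)

  same <- guarded_ratio(5, 5)
  expect_equal(same$value, 1)

  bad <- efficiency_ratios(power_w = 250, rpe = 0)
  expect_true(is.na(bad$w_per_rpe))
  expect_true(bad$w_per_rpe_invalid)

  # gross efficiency: mechanical / metabolic power x 100
  ge <- gross_efficiency(power_w = 200, vo2 = 3.0, vco2 = 2.7)
  met_w <- (3.820 * 3.0 + 1.150 * 2.7) * 4184 / 60
  expect_equal(ge, 100 * 200 / met_w)
  expect_true(ge > 15 && ge < 25)  # physiological cycling range
})

test_that("POMS indices follow the TMD and EI definitions", {
  r <- poms_derived(10, 10, 10, 10, 10, 10)
  expect_equal(r$tmd, 40)
  expect_equal(r$ei, 0)
  r2 <- poms_derived(0, 0, 0, 5, 0, 20)
  expect_equal(r2$tmd, -15)
  expect_equal(r2$ei, 15)
  expect_equal(poms_derived(0, 0, 0, 0, 0, 0), list(tmd = 0, ei = 0))
  expect_error(poms_derived(1, 2, 3, NA, 5, 6), "fatigue")

  # TMD and EI jointly pin fatigue given the other five subscales
  set.seed(9)
  s <- as.list(sample(0:30, 6))
  names(s) <- c("tension", "depression", "anger", "fatigue", "confusion",
                "vigor")
  r3 <- do.call(poms_derived, s)
  fatigue_rec <- r3$tmd - (s$tension + s$depression + s$anger + s$confusion) +
    s$vigor
  expect_equal(fatigue_rec, s$fatigue)
  expect_equal(s$vigor - r3$ei, s$fatigue)
})

test_that("initial pacing targets 117% of lactate-threshold power", {
  expect_equal(initial_pacing_target(100), 117)
  expect_equal(initial_pacing_target(156), 182.52)
  expect_equal(initial_pacing_target(202), 236.34)
  expect_error(initial_pacing_target(0), "> 0")
})

test_that("resampling yields a strict 1 Hz grid via linear interpolation", {
  s <- data.frame(time_s = c(0, 2, 5, 9), hr_bpm = c(100, 104, 110, 118))
  r <- resample_1hz(s)
  expect_equal(r$time_s, 0:9)
  expect_equal(r$hr_bpm[2], 102)  # linear between 100 @0 and 104 @2
  expect_equal(r$hr_bpm[10], 118)
  expect_error(resample_1hz(data.frame(time_s = c(0, 0, 1), hr_bpm = 1:3)),
               "strictly increasing")
})
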