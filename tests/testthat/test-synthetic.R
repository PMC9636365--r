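test_that("packaged constraints satisfy the internal consistency invariant", {
  cn <- reference_constraints()
  expect_equal(colSums(cn$parameter_counts),
               c(BL = 7, LT = 7, MT1 = 13, MT2 = 26, MAL = 44, RE = 13))
  # total scores implied by the joint distribution equal the parameter totals
  expect_equal(unname(colSums(cn$joint_cumulative)),
               unname(colSums(cn$parameter_counts)))
  # cumulative counts are non-increasing in k and bounded by cohort size
  expect_true(all(apply(cn$joint_cumulative, 2, function(v) all(diff(v) <= 0))))
  expect_true(all(cn$joint_cumulative <= cn$n_subjects))
})

test_that("reference matrix reproduces both published count tables", {
  cn <- reference_constraints()
  m <- build_reference_score_matrix(cn)
  pars <- attr(m, "parameters")
  for (ph in cn$phases) {
    blk <- m[m$phase_id == ph, ]
    expect_equal(unname(colSums(blk[, pars])),
                 unname(cn$parameter_counts[, ph]),
                 info = ph)
    for (k in 1:5)
      expect_equal(sum(blk$n_scores >= k),
                   unname(cn$joint_cumulative[k, ph]), info = paste(ph, k))
  }
  # construction is deterministic
  expect_identical(m, build_reference_score_matrix(cn))
})

test_that("classifying the reference matrix reproduces the published 3-of-5 counts", {
  cl <- classify(build_reference_score_matrix(), 3)
  flags <- tapply(cl$flagged, cl$phase_id, sum)
  expect_equal(as.numeric(flags[c("BL", "LT", "MT1", "MT2", "MAL", "RE")]),
               c(0, 0, 0, 6, 11, 0))
})

test_that("infeasible constraints raise an error naming phase and bound", {
  cn <- reference_constraints()
  # column totals without any row totals: totals disagree
  bad <- cn
  bad$joint_cumulative[, "MAL"] <- 0
  expect_error(build_reference_score_matrix(bad), "MAL")
  # a parameter count above the cohort size is caught as infeasible
  bad2 <- cn
  bad2$parameter_counts["hr_max", "BL"] <- 12
  bad2$joint_cumulative[1:2, "BL"] <- c(9, 9)
  expect_error(build_reference_score_matrix(bad2), "BL")
})

test_that("construction succeeds on random feasible margins", {
  # any actual binary matrix provides feasible margins; the deterministic
  # construction must always realize them
  set.seed(12)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    m0 <- matrix(rbinom(n * 5, 1, runif(1, 0.2, 0.8)), n, 5)
    rows <- sort(rowSums(m0), decreasing = TRUE)
    cols <- colSums(m0)
    expect_null(maladapt:::.gale_ryser_violation(rows, cols))
    m <- maladapt:::.construct_binary_matrix(rows, cols)
    expect_equal(unname(rowSums(m)), rows)
    expect_equal(unname(colSums(m)), unname(cols))
  }
})

test_that("measurement generator round trip reproduces the input matrix", {
  m <- build_reference_score_matrix()
  pars <- attr(m, "parameters")
  rescore <- function(panels) {
    bl <- compute_baselines(panels)
    score_panels(panels, bl, fixed_cutoffs())
  }
  for (seed in c(1, 2, 99)) {
    pan <- generate_measurements(m, seed = seed)
    sc <- rescore(pan)
    got <- sc[match(paste(m$subject_id, m$phase_id),
                    paste(sc$subject_id, sc$phase_id)), pars]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(m[, pars])),
                 info = paste("seed", seed))
  }
  # different seeds: different panels, identical re-scored matrix
  p1 <- generate_measurements(m, seed = 1)
  p2 <- generate_measurements(m, seed = 2)
  expect_false(isTRUE(all.equal(p1$poms_fatigue, p2$poms_fatigue)))
})

test_that("an all-zero matrix yields no deviation beyond any cut-off", {
  m <- build_reference_score_matrix()
  pars <- attr(m, "parameters")
  m[, pars] <- 0L
  m$n_scores <- 0
  pan <- generate_measurements(m, seed = 4)
  bl <- compute_baselines(pan)
  sc <- score_panels(pan, bl, fixed_cutoffs())
  expect_true(all(sc$n_scores == 0))
})

test_that("generated values stay physiologic", {
  pan <- generate_measurements(build_reference_score_matrix(), seed = 8)
  expect_true(all(pan$hr_max > 0))
  expect_true(all(pan$glucose_end >= 0))
  expect_true(all(pan$lactate_end >= 0))
  expect_true(all(pan$rpe_mean >= 6 & pan$rpe_mean <= 20))
})

test_that("respiration generator reproduces the configured effect", {
  # zero noise: maladaptive respiration is exactly 60% of the subject mean
  cfg0 <- generator_config(respiration_within_sd = 0)
  r0 <- generate_respiration(cfg0, seed = 3)
  d0 <- respiration_deltas(r0)
  mal <- d0[d0$phase_id == "MAL", ]
  expect_equal(mal$respiration, 0.6 * mal$normal_respiration,
               tolerance = 1e-12)

  # per-subject deltas across normal phases sum to ~0 under noise
  r <- generate_respiration(seed = 6)
  d <- respiration_deltas(r)
  norm <- d[d$phase_id != "MAL", ]
  sums <- tapply(norm$delta, norm$subject_id, sum)
  expect_equal(c(sums), rep(0, length(sums)), ignore_attr = TRUE, tolerance = 1e-9)

  # no biopsy phase is emitted for MT2
  expect_false("MT2" %in% r$phase_id)
})

test_that("large-cohort respiration reduction approaches the configured 40%", {
  r <- generate_respiration(n_subjects = 1000, seed = 10)
  d <- respiration_deltas(r)
  normal_mean <- mean(d$respiration[d$phase_id != "MAL"])
  mal_mean <- mean(d$respiration[d$phase_id == "MAL"])
  expect_equal(100 * (1 - mal_mean / normal_mean), 40, tolerance = 0.05)
})

test_that("simulated effect-model cohorts separate MAL from normal phases", {
  pan <- simulate_cohort(seed = 21)
  rep <- run_pipeline(pan, cutoff_mode = "fixed")
  flags <- tapply(rep$classification$flagged, rep$classification$phase_id, sum)
  expect_equal(unname(flags["MAL"]), 11)
  expect_true(all(flags[c("BL", "LT", "MT1", "RE")] <= 1))
})

test_that("generated sessions have the prescribed 5 x 4'3 structure", {
  s <- generate_session(seed = 31)
  iv <- s$markers[startsWith(s$markers$label, "interval"), ]
  expect_equal(nrow(iv), 5)
  expect_equal(iv$end_s - iv$start_s + 1, rep(240, 5))
  expect_equal(s$markers$start_s[1], 0)
  expect_equal(nrow(s$series), 600 + 120 + 5 * (240 + 180))
  expect_equal(diff(s$series$time_s), rep(1, nrow(s$series) - 1))
  expect_true(all(s$series$hr_bpm > 0))
  expect_true(all(s$series$power_w >= 0))

  # the session HR peak lies within an interval segment
  pk <- rolling_window_peak(s$series$hr_bpm, 30, time = s$series$time_s)
  lab <- s$series$label[s$series$time_s == pk$start_time]
  expect_true(startsWith(lab, "interval"))

  # recovery decay gives positive HRR at 30 s
  hrr <- heart_rate_recovery(s$series, iv, timepoints = 30)
  expect_true(all(hrr$per_bout$hrr_30 > 0))
})
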