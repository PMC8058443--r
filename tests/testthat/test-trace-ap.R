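test_that("segmentation finds every paced beat and nothing on flat traces", {
  tr <- gen_ap_train(ap_train_spec(n_beats = 30, seed = 2))
  expect_length(segment_aps(tr), 30)

  flat <- voltage_trace(rep(-80, 5000), 10)
  expect_warning(segs <- segment_aps(flat), "no action potentials")
  expect_length(segs, 0)

  # stimulus annotations and threshold detection agree on clean data
  tr2 <- gen_ap_train(ap_train_spec(n_beats = 10, apd90_sd = 8, seed = 5))
  with_stim <- segment_aps(tr2)
  tr2$stimulus_times <- NULL
  without <- segment_aps(tr2)
  expect_equal(vapply(with_stim, `[[`, 0, "takeoff_time"),
               vapply(without, `[[`, 0, "takeoff_time"))
})

test_that("triangle AP yields analytic APD50/APD90 and upstroke velocity", {
  fs <- 10
  tr <- make_triangle_ap(fs = fs)
  f <- ap_features(segment_aps(tr)[[1]])
  expect_lt(abs(f$apd50 - 150), 1 / fs)
  expect_lt(abs(f$apd90 - 270), 1 / fs)
  expect_equal(f$e_diast, -80)
  expect_gte(f$apd90, f$apd50)

  # 120 mV linear upstroke over 1.2 ms -> dV/dt_max = 100 V/s
  t <- seq(0, 500, by = 1 / fs)
  v <- rep(-80, length(t))
  ris <- t > 100 & t <= 101.2
  v[ris] <- -80 + 120 * (t[ris] - 100) / 1.2
  v[t > 101.2 & t <= 401.2] <- 40 - 120 * (t[t > 101.2 & t <= 401.2] - 101.2) / 300
  v[t > 401.2] <- -80
  f2 <- ap_features(segment_aps(voltage_trace(v, fs, stimulus_times = 100))[[1]])
  expect_equal(f2$dvdt_max, 100, tolerance = 1e-6)
})

test_that("APD estimates match generator ground truth within one sample", {
  tr <- gen_ap_train(ap_train_spec(n_beats = 15, apd90_sd = 10, seed = 11))
  gt <- ground_truth(tr)$beats
  ft <- ap_features_table(segment_aps(tr))
  expect_lt(max(abs(ft$apd90 - gt$apd90)), 1 / tr$sampling_rate + 1e-9)
  expect_lt(max(abs(ft$apd50 - gt$apd50)), 1 / tr$sampling_rate + 1e-9)
  expect_true(all(ft$apd90 >= ft$apd50))
})

test_that("a non-repolarizing AP is flagged missing, not extrapolated", {
  fs <- 10
  t <- seq(0, 800, by = 1 / fs)
  v <- rep(-80, length(t))
  v[t > 100] <- 40 - 30 * (t[t > 100] - 100) / 700  # never reaches the 90% level
  f <- ap_features(segment_aps(voltage_trace(v, fs, stimulus_times = 100))[[1]])
  expect_true(is.na(f$apd90))
  expect_true("apd90" %in% f$missing)
})

test_that("DAD rule is inclusive at 1 mV and events are located precisely", {
  expect_equal(nrow(detect_dads(make_dad_trace(0.9))), 0)
  expect_equal(nrow(detect_dads(make_dad_trace(1.0))), 1)
  d <- detect_dads(make_dad_trace(1.5))
  expect_equal(nrow(d), 1)
  expect_equal(d$amplitude, 1.5, tolerance = 1e-6)
  expect_true(attr(d, "has_dads"))
  expect_false(attr(detect_dads(make_dad_trace(0.9)), "has_dads"))
})

test_that("DAD detection has perfect recall and precision on noisy trains", {
  tr <- gen_ap_train(ap_train_spec(n_beats = 25, dad_probability = 0.5,
                                   dad_amplitude = 1.5, noise_sd = 0.2,
                                   seed = 7))
  truth <- ground_truth(tr)$dads
  det <- detect_dads(tr)
  matched <- vapply(truth$time, function(tt) any(abs(det$time - tt) <= 20), TRUE)
  expect_true(all(matched))                      # recall = 1
  expect_equal(nrow(det), nrow(truth))           # precision = 1
})

test_that("EAD detection flags plateau re-depolarizations only", {
  tr <- gen_ap_train(ap_train_spec(n_beats = 3, seed = 2))
  segs <- segment_aps(tr)
  expect_length(detect_eads(segs[[2]]), 0)       # monotone repolarization

  # inject a sharp 8 mV bump on the repolarization phase of beat 2 (steep
  # enough to reverse the ~0.5 mV/ms repolarization locally)
  t <- trace_times(tr)
  rel <- t - 1300
  sel <- rel >= 0 & rel <= 30
  tr$samples[sel] <- tr$samples[sel] + 8 * 0.5 * (1 - cos(2 * pi * rel[sel] / 30))
  segs2 <- segment_aps(tr)
  expect_length(detect_eads(segs2[[2]]), 1)
  # below the minimum-deflection setting: not flagged
  expect_length(detect_eads(segs2[[2]], min_deflection = 8), 0)
})

test_that("STV matches its definition and invariances", {
  expect_equal(stv(rep(250, 30))$stv, 0)

  alt <- rep(c(200, 210), 15)
  r <- stv(alt)
  expect_equal(r$stv, 290 / (30 * sqrt(2)), tolerance = 1e-12)
  expect_equal(nrow(r$poincare_pairs), 29)

  # translation invariance and linear scaling
  x <- with_seed(1, rnorm(30, 250, 10))
  expect_equal(stv(x)$stv, stv(x + 57)$stv, tolerance = 1e-12)
  expect_equal(stv(3 * x)$stv, 3 * stv(x)$stv, tolerance = 1e-12)

  # alternative denominator convention
  expect_equal(stv(alt, denominator = "two")$stv, 290 / 60, tolerance = 1e-12)

  expect_error(stv(250), "at least 2")
})

test_that("STV-APD90 regression recovers exact and simulated slopes", {
  apd <- seq(200, 300, length.out = 10)
  r <- stv_apd_regression(data.frame(apd90 = apd, stv = 0.05 * apd))
  expect_equal(r$slope, 0.05, tolerance = 1e-12)
  expect_equal(r$r, 1, tolerance = 1e-12)

  # two points: exact interpolating slope
  r2 <- stv_apd_regression(data.frame(apd90 = c(200, 300), stv = c(4, 9)))
  expect_equal(r2$slope, 0.05, tolerance = 1e-12)

  expect_error(stv_apd_regression(data.frame(apd90 = rep(250, 5),
                                             stv = rnorm(5))), "degenerate")

  # simulated groups share a common slope
  sim <- with_seed(4, {
    lapply(1:3, function(g) {
      apd <- runif(25, 200, 320)
      data.frame(apd90 = apd, stv = 2 + 0.04 * apd + rnorm(25, 0, 0.8))
    })
  })
  slopes <- vapply(sim, function(d) stv_apd_regression(d)$slope, 0)
  expect_true(all(abs(slopes - 0.04) < 0.02))
})
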