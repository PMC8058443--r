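test_that("F/F0 normalization is exact on identities and invariant to gain", {
  flat <- fluorescence_trace(rep(100, 2000), 2000, background = 0)
  expect_true(all(abs(normalize_f(flat)$samples - 1) < 1e-12))

  # peak at 2*F0 -> F/F0 = 2, dF/F0 = 1
  y <- rep(100, 4000); y[2000:2100] <- 200
  tr <- fluorescence_trace(y, 2000, background = 0)
  expect_equal(max(normalize_f(tr)$samples), 2)

  # generator round trip: known amplitude recovered within 2% (noiseless)
  ct <- gen_ca_trace(stim_rate = 1, transient_amplitude = 1, decay_tau = 200,
                     noise_sd = 0, seed = 3)
  ss <- attr(transient_features(normalize_f(ct)), "steady_state")
  expect_lt(abs(ss$amplitude - 1), 0.02)

  # affine invariance of the normalized trace (gain and offset as background)
  gain <- 3.7; offset <- 25
  ct2 <- ct; ct2$samples <- gain * ct$samples + offset
  ct2$background <- gain * ct$background + offset
  expect_equal(normalize_f(ct2)$samples, normalize_f(ct)$samples,
               tolerance = 1e-9)

  bad <- fluorescence_trace(rep(100, 100), 2000, background = 150)
  expect_error(normalize_f(bad), "non-physical")
})

test_that("half-decay time equals tau * log(2) for mono-exponential decays", {
  ct <- gen_ca_trace(stim_rate = 1, n_transients = 1, transient_amplitude = 1,
                     decay_tau = 200, noise_sd = 0, duration = 2500, seed = 1)
  tf <- transient_features(normalize_f(ct))
  expect_lt(abs(tf$t_half - 200 * log(2)), 0.5)  # one sample at 2 kHz
  expect_equal(tf$decay_tau, 200, tolerance = 1e-3)

  # tau sweep: fitted tau within 5% on noiseless data
  for (tau in c(100, 500, 2000)) {
    ct2 <- gen_ca_trace(stim_rate = 1, n_transients = 1, decay_tau = tau,
                        noise_sd = 0, duration = 6 * tau + 1000, seed = 1)
    tf2 <- transient_features(normalize_f(ct2))
    expect_lt(abs(tf2$t_half - tau * log(2)), 0.5)
    expect_lt(abs(tf2$decay_tau - tau) / tau, 0.05)
  }
})

test_that("degenerate and rate-dependent transients are handled", {
  # amplitude 0: no crash, kinetics flagged missing
  ct <- gen_ca_trace(stim_rate = 1, transient_amplitude = 0, n_transients = 3,
                     noise_sd = 0, duration = 4000, seed = 1)
  tf <- transient_features(normalize_f(ct), stim_times = c(500, 1500, 2500))
  expect_equal(nrow(tf), 3)
  expect_true(all(is.na(tf$t_half)))

  # rate-dependent tau ordering survives the round trip
  t_half <- vapply(list(c(1, 250), c(2, 180), c(4, 120)), function(p) {
    ct <- gen_ca_trace(stim_rate = p[1], decay_tau = p[2], n_transients = 8,
                       noise_sd = 0, seed = 2)
    attr(transient_features(normalize_f(ct)), "steady_state")$t_half
  }, 0)
  expect_true(all(diff(t_half) < 0))
})

test_that("caffeine transient yields CaSR and NCX tau by mono-exponential fit", {
  cf <- gen_ca_trace(stim_rate = 0, caffeine_time = 2000,
                     caffeine_amplitude = 0.8, caffeine_tau = 800,
                     noise_sd = 0, duration = 8000, seed = 3)
  ca <- caffeine_analysis(normalize_f(cf))
  expect_lt(abs(ca$casr - 0.8), 0.8 * 0.02)
  expect_lt(abs(ca$ncx_tau - 800), 1)

  # 5% noise: tau within 5% (fixed seed)
  cf2 <- gen_ca_trace(stim_rate = 0, caffeine_time = 2000,
                      caffeine_amplitude = 0.8, caffeine_tau = 800,
                      noise_sd = 0.05 * 0.8 * 100, duration = 8000, seed = 5)
  ca2 <- caffeine_analysis(normalize_f(cf2))
  expect_lt(abs(ca2$ncx_tau - 800) / 800, 0.05)

  # a non-decaying segment must error, not silently return
  y <- rep(1, 6000); y[4000:6000] <- 1.8
  nd <- fluorescence_trace(100 * y, 2000, background = 0, caffeine_time = 2000)
  expect_error(caffeine_analysis(normalize_f(nd, f0 = 100)), "decay|fit")
})

test_that("wave rule is a strict >3 SD threshold with run-length support", {
  # deterministic boundary check with a known SD
  n <- 20000; s <- 0.05
  mk <- function(k) {
    y <- rep(1, n)
    rel <- seq_len(601) - 1
    y[5000 + rel] <- 1 + (k * s) * 0.5 * (1 - cos(2 * pi * rel / 600))
    fluorescence_trace(y, 2000, background = 0)
  }
  ev29 <- detect_resting_events(mk(2.9), f_rest = 1, f_rest_sd = s)
  expect_equal(nrow(ev29), 0)
  ev35 <- detect_resting_events(mk(3.5), f_rest = 1, f_rest_sd = s)
  expect_equal(nrow(ev35), 1)
  expect_equal(ev35$kind, "wave")
  expect_true(attr(ev35, "has_waves"))

  # 6-SD events: identical count at cutoffs 3, 4 and 5 SD (noisy, fixed seed)
  we <- data.frame(time = c(10000, 30000), amplitude = c(0.3, 0.3))
  rt <- gen_ca_trace(stim_rate = 0, wave_events = we, noise_sd = 5,
                     duration = 60000, seed = 9)
  nr <- normalize_f(rt)
  counts <- vapply(c(3, 4, 5), function(k)
    nrow(detect_resting_events(nr, sd_cutoff = k)), 0L)
  expect_equal(counts, rep(2L, 3))

  # large events are labeled resting transients
  big <- gen_ca_trace(stim_rate = 0,
                      wave_events = data.frame(time = 10000, amplitude = 0.9),
                      noise_sd = 5, duration = 30000, seed = 4)
  evb <- detect_resting_events(normalize_f(big))
  expect_equal(evb$kind, "resting_transient")
})

test_that("wave detector has no false positives on noise-only traces", {
  fp <- 0L
  for (s in 1:100) {
    x <- normalize_f(gen_ca_trace(stim_rate = 0, noise_sd = 5,
                                  duration = 20000, seed = 4000 + s))
    fp <- fp + nrow(detect_resting_events(x))
  }
  expect_equal(fp, 0L)
})

test_that("normalization to control propagates means and errors per rate", {
  tr <- data.frame(cycle_length = rep(c(250, 500, 1000), each = 6),
                   value = rep(0.8, 18))
  ctl <- data.frame(cycle_length = rep(c(250, 500, 1000), each = 6),
                    value = rep(1, 18))
  out <- normalize_to_ctrl(tr, ctl)
  expect_equal(out$ratio, rep(0.8, 3))

  # identical tables -> all ratios 1
  out2 <- normalize_to_ctrl(ctl, ctl)
  expect_equal(out2$ratio, rep(1, 3))

  # simulated 20% deficit recovered at every rate
  sim <- with_seed(8, {
    cl <- rep(c(250, 500, 1000), each = 40)
    list(t = data.frame(cycle_length = cl, value = rnorm(120, 0.8, 0.05)),
         c = data.frame(cycle_length = cl, value = rnorm(120, 1.0, 0.05)))
  })
  out3 <- normalize_to_ctrl(sim$t, sim$c)
  expect_true(all(abs(out3$ratio - 0.8) < 0.05))
  expect_true(all(out3$se > 0))

  # missing control level is reported by name
  expect_error(normalize_to_ctrl(
    data.frame(cycle_length = 125, value = 1), ctl), "125")
})
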