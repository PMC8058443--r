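test_that("generators are deterministic given a seed and leave the RNG alone", {
  a <- gen_ap_train(ap_train_spec(n_beats = 5, apd90_sd = 10, dad_probability = 0.5,
                                  noise_sd = 0.1, seed = 42))
  b <- gen_ap_train(ap_train_spec(n_beats = 5, apd90_sd = 10, dad_probability = 0.5,
                                  noise_sd = 0.1, seed = 42))
  expect_identical(a$samples, b$samples)
  expect_identical(ground_truth(a), ground_truth(b))

  set.seed(777); before <- runif(1)
  set.seed(777)
  invisible(gen_linescan(linescan_spec(n_lines = 32, n_pixels = 32, seed = 9)))
  expect_identical(runif(1), before)

  sp <- with_seed(3, data.frame(
    x_um = runif(20, 10, 66), t_ms = runif(20, 50, 970),
    amplitude = runif(20, 0.4, 1.2), sigma_um = 1, rise_ms = 10, tau_ms = 30))
  i1 <- gen_linescan(linescan_spec(sparks = sp, seed = 5))
  i2 <- gen_linescan(linescan_spec(sparks = sp, seed = 5))
  expect_identical(i1$matrix, i2$matrix)
  expect_equal(nrow(ground_truth(i1)$sparks), 20)
})

test_that("AP train ground truth matches the requested statistics", {
  # zero-variability: every beat identical, STV of the truth is exactly 0
  tr0 <- gen_ap_train(ap_train_spec(apd90_sd = 0, dad_probability = 0, seed = 1))
  gt0 <- ground_truth(tr0)
  expect_equal(stats::sd(gt0$beats$apd90), 0)
  expect_equal(stv(gt0$beats$apd90)$stv, 0)

  # drawn APD90 SD close to the requested 10 ms
  tr <- gen_ap_train(ap_train_spec(n_beats = 30, apd90_mean = 250,
                                   apd90_sd = 10, seed = 7))
  gt <- ground_truth(tr)
  expect_lt(abs(stats::sd(gt$beats$apd90) - 10), 3.5)
  expect_true(all(gt$beats$apd90 >= gt$beats$apd50))

  # probability-1 DADs: exactly one per diastole
  trd <- gen_ap_train(ap_train_spec(n_beats = 12, dad_probability = 1,
                                    dad_amplitude = 3, seed = 3))
  expect_equal(nrow(ground_truth(trd)$dads), 12)
})

test_that("AP train spec rejects non-physical settings", {
  expect_error(ap_train_spec(sampling_rate = 0), "sampling_rate")
  expect_error(ap_train_spec(pacing_rate = 5, apd90_mean = 250), "refractory")
  expect_error(ap_train_spec(dad_probability = 1.5), "dad_probability")
  expect_error(ap_train_spec(peak_potential = -90), "peak_potential")
})

test_that("fluorescence generator produces analytic decays and a clean baseline", {
  # noiseless, no events: constant raw trace; F/F0 identically 1
  flat <- gen_ca_trace(stim_rate = 0, noise_sd = 0, duration = 3000, seed = 1)
  expect_equal(diff(range(flat$samples)), 0)
  expect_true(all(abs(normalize_f(flat)$samples - 1) < 1e-12))

  # decay tau 200 -> true half-decay 138.63 ms recorded in ground truth
  ct <- gen_ca_trace(decay_tau = 200, n_transients = 1, duration = 2500, seed = 1)
  expect_equal(ground_truth(ct)$t_half, 200 * log(2))

  expect_error(gen_ca_trace(transient_amplitude = -1), "amplitude")
  expect_error(gen_ca_trace(decay_tau = -5), "tau")
})

test_that("line-scan generator renders separable kernels with known geometry", {
  # no sparks, no noise: constant at background + f0
  img0 <- gen_linescan(linescan_spec(n_lines = 64, n_pixels = 64, noise_sd = 0,
                                     seed = 1))
  expect_equal(diff(range(img0$matrix)), 0)
  expect_equal(img0$matrix[1, 1], 110)

  # Gaussian FWHM identity on a noiseless spark
  sp <- data.frame(x_um = 38.4, t_ms = 512, amplitude = 1, sigma_um = 1.2,
                   rise_ms = 10, tau_ms = 30)
  img <- gen_linescan(linescan_spec(sparks = sp, noise_sd = 0, seed = 1))
  gt <- ground_truth(img)$sparks
  expect_equal(gt$fwhm_um, 2 * sqrt(2 * log(2)) * 1.2)
  # spatial slice at the peak line crosses half max at +/- FWHM/2
  pk_row <- round(512 / 2) + 1
  prof <- (img$matrix[pk_row, ] - 110) / 100
  xs <- (seq_along(prof) - 1) * 0.15
  half_w <- sum(prof >= max(prof) / 2) * 0.15
  expect_lt(abs(half_w - gt$fwhm_um), 2 * 0.15)

  expect_error(linescan_spec(sparks = data.frame(
    x_um = 500, t_ms = 100, amplitude = 1, sigma_um = 1, rise_ms = 10,
    tau_ms = 30)), "outside")
})

test_that("striation generator controls spacing, dropout and masking", {
  expect_error(striation_spec(sarcomere_spacing = 0.1), "2 pixels")
  img <- gen_striation_image(striation_spec(width = 256, height = 64, seed = 1))
  expect_equal(ground_truth(img)$frequency_um1, 0.5)
  expect_true(all(img$matrix >= 0 & img$matrix <= 255))

  # dropout 1: no striations at all
  img1 <- gen_striation_image(striation_spec(width = 256, height = 64,
                                             dropout_fraction = 1, seed = 1))
  expect_equal(diff(range(img1$matrix)), 0)
})
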