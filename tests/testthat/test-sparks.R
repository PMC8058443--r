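test_that("spark mass follows the amplitude * 1.206 * FWHM^3 formula", {
  expect_equal(spark_mass(0, 2), 0)
  expect_equal(spark_mass(0.5, 2), 0.5 * 1.206 * 8)
  expect_equal(spark_mass(0.5, 4) / spark_mass(0.5, 2), 8)  # cubic scaling
  expect_error(spark_mass(-0.1, 1), "non-negative")
  expect_error(spark_mass(0.5, -1), "non-negative")
})

test_that("spark frequency is events per second per 100 um", {
  sp <- data.frame(in_focus = rep(TRUE, 5), partial = rep(FALSE, 5))
  expect_equal(spark_frequency(sp, scan_duration = 10, line_length = 50), 1)
  expect_equal(spark_frequency(sp[0, ], 10, 50), 0)
  expect_error(spark_frequency(sp, 0, 50), "scan_duration")

  # 10 frames of 512 lines at 2 ms/line: duration 10.24 s enters the rate
  frames <- lapply(1:10, function(i)
    gen_linescan(linescan_spec(n_lines = 512, n_pixels = 64, noise_sd = 5,
                               seed = i))$matrix)
  stack <- linescan_image(do.call(rbind, frames), pixel_size = 0.15,
                          line_period = 2, background = 10)
  st <- analyze_sparks(stack)
  expect_equal(attr(st, "scan_duration"), 10.24)
})

test_that("ember and in-focus rules are strict/inclusive exactly as defined", {
  sp <- data.frame(x_center = 1:3, t_center = 1:3,
                   amplitude = c(0.5, 0.5, 0.25),
                   fwhm = 2, fdhm = c(25, 20, 25), fw = 3, fd = 30, ttp = 5,
                   tau_decay = 20, mass = spark_mass(c(0.5, 0.5, 0.25), 2),
                   in_focus = c(0.5, 0.5, 0.25) > 0.3,
                   is_ember = c(25, 20, 25) > 20, partial = FALSE)
  expect_equal(sp$is_ember, c(TRUE, FALSE, TRUE))   # FDHM 20 is NOT an ember
  expect_equal(sp$in_focus, c(TRUE, TRUE, FALSE))   # amplitude 0.25 excluded
  s <- summarize_sparks(sp, scan_duration = 10, line_length = 50)
  expect_equal(s$n_sparks, 2)          # the out-of-focus spark is excluded
  expect_equal(s$ember_count, 1)
  expect_equal(s$frequency, 2 / 10 / 0.5)
  expect_equal(s$leak, s$mean_mass * s$frequency)
  expect_equal(s$mean_mass, mean(spark_mass(c(0.5, 0.5), 2)))

  # leak product identity on explicit numbers
  sp2 <- sp[1:2, ]; sp2$mass <- c(4, 4)
  s2 <- summarize_sparks(sp2, scan_duration = 10, line_length = 80)
  expect_equal(s2$leak, 4 * (2 / 10 / 0.8))
})

test_that("detection is deterministic, silent on constants, monotone in cri", {
  const <- linescan_image(matrix(100, 64, 64), 0.15, 2)
  expect_warning(d0 <- detect_sparks(const), "zero-variance")
  expect_equal(d0$n, 0)

  sp <- data.frame(x_um = c(20, 50), t_ms = c(300, 700),
                   amplitude = c(0.5, 1.0), sigma_um = 1, rise_ms = 10,
                   tau_ms = 30)
  img <- gen_linescan(linescan_spec(sparks = sp, noise_sd = 10, seed = 3))
  d1 <- detect_sparks(img); d2 <- detect_sparks(img)
  expect_identical(lapply(d1$regions, `[[`, "pixels"),
                   lapply(d2$regions, `[[`, "pixels"))

  counts <- vapply(c(2.5, 3.8, 5, 8), function(cri)
    detect_sparks(img, cri = cri)$n, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[2], 2L)  # both sparks found at the default criterion
})

test_that("in-focus rule filters amplitude <= 0.3 events from summaries", {
  sp <- data.frame(x_um = c(20, 55), t_ms = c(300, 700),
                   amplitude = c(0.25, 1.0), sigma_um = 1, rise_ms = 10,
                   tau_ms = 30)
  img <- gen_linescan(linescan_spec(sparks = sp, noise_sd = 2, seed = 6))
  st <- analyze_sparks(img)
  dim_spark <- which(abs(st$x_center - 20) < 2)
  expect_false(st$in_focus[dim_spark])
  s <- summarize_sparks(st)
  expect_equal(s$n_sparks, 1)
})

test_that("parameters recover ground truth on simulated sparks", {
  batch <- make_spark_batch(n_images = 4, per_image = 5, seed = 9000)
  errs <- list(amp = c(), fwhm = c(), fdhm = c(), tau = c())
  found <- 0L
  for (im in seq_along(batch$images)) {
    st <- analyze_sparks(batch$images[[im]])
    gt <- batch$truth[batch$truth$image == im, ]
    idx <- match_sparks(st, gt)
    found <- found + sum(!is.na(idx))
    ok <- !is.na(idx)
    errs$amp <- c(errs$amp, abs(st$amplitude[idx[ok]] - gt$amplitude[ok]) / gt$amplitude[ok])
    errs$fwhm <- c(errs$fwhm, abs(st$fwhm[idx[ok]] - gt$fwhm_um[ok]) / gt$fwhm_um[ok])
    errs$fdhm <- c(errs$fdhm, abs(st$fdhm[idx[ok]] - gt$fdhm_ms[ok]) / gt$fdhm_ms[ok])
    errs$tau <- c(errs$tau, abs(st$tau_decay[idx[ok]] - gt$tau_ms[ok]) / gt$tau_ms[ok])
  }
  expect_gte(found / nrow(batch$truth), 0.95)
  expect_lt(stats::median(errs$amp), 0.10)
  expect_lt(stats::median(errs$fwhm), 0.15)
  expect_lt(stats::median(errs$fdhm), 0.20)
  expect_lt(stats::median(errs$tau), 0.20)
})

test_that("edge sparks are flagged partial and excluded from summaries", {
  sp <- data.frame(x_um = c(0.5, 40), t_ms = c(500, 500),
                   amplitude = 1, sigma_um = 1, rise_ms = 10, tau_ms = 30)
  img <- gen_linescan(linescan_spec(sparks = sp, noise_sd = 5, seed = 2))
  st <- analyze_sparks(img)
  edge <- which(st$x_center < 3)
  expect_true(length(edge) == 0 || any(st$partial[edge]))
  s <- summarize_sparks(st)
  expect_equal(s$n_sparks, sum(st$in_focus & !st$partial))
})
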