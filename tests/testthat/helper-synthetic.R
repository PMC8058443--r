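# Shared fixtures, all built in code.

# Triangle AP: instantaneous upstroke dia -> peak at t = t_up, linear
# repolarization back to dia over repol_ms, sampled at fs kHz.
make_triangle_ap <- function(fs = 10, dia = -80, peak = 40, t_up = 100,
                             repol_ms = 300, total = 1000) {
  t <- seq(0, total, by = 1 / fs)
  v <- rep(dia, length(t))
  ramp <- t > t_up & t <= t_up + repol_ms
  v[ramp] <- peak - (peak - dia) * (t[ramp] - t_up) / repol_ms
  voltage_trace(v, fs, stimulus_times = t_up)
}

# A voltage trace that is one AP with a raised-cosine diastolic hump of
# given amplitude; two beats so the hump sits in a well-defined diastole.
make_dad_trace <- function(amplitude, fs = 10) {
  spec <- ap_train_spec(n_beats = 2, dad_probability = 0, seed = 1,
                        sampling_rate = fs)
  tr <- gen_ap_train(spec)
  t <- trace_times(tr)
  center <- 200 + 600  # mid-diastole of beat 1
  width <- 50
  rel <- t - (center - width / 2)
  sel <- rel >= 0 & rel <= width
  tr$samples[sel] <- tr$samples[sel] +
    amplitude * 0.5 * (1 - cos(2 * pi * rel[sel] / width))
  tr
}

# Batch of spark-bearing line-scan images with well-separated events.
# Returns list(images, truth): truth has one row per ground-truth spark
# with its image index attached.
make_spark_batch <- function(n_images = 10, per_image = 5, noise_sd = 10,
                             amp_range = c(0.5, 1.5), seed = 5000) {
  images <- vector("list", n_images)
  truth <- vector("list", n_images)
  for (im in seq_len(n_images)) {
    layout <- with_seed(seed + 31 * im, {
      data.frame(
        x_um = seq(10, 66, length.out = per_image) + runif(per_image, -3, 3),
        t_ms = seq(120, 900, length.out = per_image) + runif(per_image, -30, 30),
        amplitude = runif(per_image, amp_range[1], amp_range[2]),
        sigma_um = runif(per_image, 0.8, 1.3),
        rise_ms = runif(per_image, 5, 15),
        tau_ms = runif(per_image, 20, 40))
    })
    img <- gen_linescan(linescan_spec(sparks = layout, noise_sd = noise_sd,
                                      seed = seed + im))
    images[[im]] <- img
    gt <- ground_truth(img)$sparks
    gt$image <- im
    truth[[im]] <- gt
  }
  list(images = images, truth = do.call(rbind, truth))
}

# Match detected sparks to ground truth by peak position (within dx um and
# dt ms); returns per-truth-row index into the detection table (NA = miss).
match_sparks <- function(detected, truth, dx = 2, dt = 20) {
  vapply(seq_len(nrow(truth)), function(i) {
    hit <- which(abs(detected$x_center - truth$x_um[i]) < dx &
                 abs(detected$t_center - truth$t_ms[i]) < dt)
    if (length(hit)) hit[1L] else NA_integer_
  }, 1L)
}
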