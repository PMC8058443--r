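#' Specification of a synthetic paced action-potential train
#'
#' The waveform template is piecewise analytic — a linear upstroke of
#' `rise_time` ms, a flat plateau of `plateau_time` ms, and a linear
#' repolarization whose duration is chosen per beat so that the true APD90
#' equals the per-beat draw from `N(apd90_mean, apd90_sd)`. All ground-truth
#' durations are therefore closed-form. DADs are raised-cosine diastolic
#' humps inserted with probability `dad_probability` per diastole.
#'
#' @param n_beats number of paced beats (>= 1).
#' @param pacing_rate pacing rate (Hz).
#' @param apd90_mean,apd90_sd mean and beat-to-beat SD of APD90 (ms).
#' @param diastolic_potential,peak_potential resting and peak potential (mV).
#' @param dad_probability per-diastole probability of one DAD event.
#' @param dad_amplitude,dad_width DAD peak amplitude (mV) and base width (ms).
#' @param noise_sd additive Gaussian noise SD (mV).
#' @param sampling_rate sampling rate (kHz).
#' @param rise_time,plateau_time upstroke and plateau durations (ms).
#' @param lead_in diastolic lead-in before the first stimulus (ms).
#' @param seed integer RNG seed (required for reproducibility).
#' @return an `APTrainSpec` list.
#' @export
ap_train_spec <- function(n_beats = 30L, pacing_rate = 1, apd90_mean = 250,
                          apd90_sd = 0, diastolic_potential = -80,
                          peak_potential = 40, dad_probability = 0,
                          dad_amplitude = 2, dad_width = 50, noise_sd = 0,
                          sampling_rate = 10, rise_time = 1, plateau_time = 20,
                          lead_in = 200, seed = 1L) {
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (apd90_sd < 0) stop("apd90_sd must be >= 0")
  if (dad_probability < 0 || dad_probability > 1)
    stop("dad_probability must be in [0, 1]")
  if (peak_potential <= diastolic_potential)
    stop("peak_potential must exceed diastolic_potential")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (pacing_rate <= 0) stop("pacing_rate must be positive")
  if (apd90_mean <= rise_time + plateau_time)
    stop("apd90_mean must exceed rise_time + plateau_time")
  # refractory margin: the cell must fully repolarize well before re-pacing
  if (1000 / pacing_rate < apd90_mean + 100)
    stop("pacing period shorter than APD plus refractory margin")
  structure(
    list(n_beats = as.integer(n_beats), pacing_rate = pacing_rate,
         apd90_mean = apd90_mean, apd90_sd = apd90_sd,
         diastolic_potential = diastolic_potential,
         peak_potential = peak_potential,
         dad_probability = dad_probability, dad_amplitude = dad_amplitude,
         dad_width = dad_width, noise_sd = noise_sd,
         sampling_rate = sampling_rate, rise_time = rise_time,
         plateau_time = plateau_time, lead_in = lead_in, seed = seed),
    class = "APTrainSpec"
  )
}

#' Generate a paced action-potential train with known ground truth
#'
#' @param spec an [ap_train_spec()].
#' @return a `VoltageTrace` with a `ground_truth` attribute holding
#'   `beats` (per-beat stimulus/take-off times and true APD50/APD90) and
#'   `dads` (event peak times and amplitudes).
#' @export
gen_ap_train <- function(spec) {
  stopifnot(inherits(spec, "APTrainSpec"))
  with_seed(spec$seed, {
    fs <- spec$sampling_rate
    period <- 1000 / spec$pacing_rate
    stim <- spec$lead_in + (seq_len(spec$n_beats) - 1) * period
    total <- spec$lead_in + spec$n_beats * period
    n <- round(total * fs) + 1L
    t <- (seq_len(n) - 1) / fs
    dia <- spec$diastolic_potential
    peak <- spec$peak_potential
    amp <- peak - dia
    v <- rep(dia, n)

    apd90 <- stats::rnorm(spec$n_beats, spec$apd90_mean, spec$apd90_sd)
    floor90 <- spec$rise_time + spec$plateau_time + 20
    apd90 <- pmax(apd90, floor90)
    D <- (apd90 - spec$rise_time - spec$plateau_time) / 0.9
    apd50 <- spec$rise_time + spec$plateau_time + 0.5 * D

    for (b in seq_len(spec$n_beats)) {
      rel <- t - stim[b]
      r1 <- spec$rise_time
      r2 <- r1 + spec$plateau_time
      r3 <- r2 + D[b]
      sel <- rel >= 0 & rel < r1
      v[sel] <- dia + amp * rel[sel] / r1
      sel <- rel >= r1 & rel < r2
      v[sel] <- peak
      sel <- rel >= r2 & rel < r3
      v[sel] <- peak - amp * (rel[sel] - r2) / D[b]
    }

    dad_t <- numeric(0); dad_a <- numeric(0)
    for (b in seq_len(spec$n_beats)) {
      if (stats::runif(1) < spec$dad_probability) {
        d0 <- stim[b] + apd90[b] + 80
        d1 <- stim[b] + period - 80 - spec$dad_width
        center <- if (d1 > d0) stats::runif(1, d0 + spec$dad_width / 2,
                                            d1 + spec$dad_width / 2)
                  else stim[b] + apd90[b] + (period - apd90[b]) / 2
        center <- round(center * fs) / fs  # snap peak to the sample grid
        t0 <- center - spec$dad_width / 2
        rel <- t - t0
        sel <- rel >= 0 & rel <= spec$dad_width
        v[sel] <- v[sel] +
          spec$dad_amplitude * 0.5 * (1 - cos(2 * pi * rel[sel] / spec$dad_width))
        dad_t <- c(dad_t, center)
        dad_a <- c(dad_a, spec$dad_amplitude)
      }
    }
    if (spec$noise_sd > 0) v <- v + stats::rnorm(n, 0, spec$noise_sd)

    trace <- voltage_trace(v, fs, stimulus_times = stim)
    attr(trace, "ground_truth") <- list(
      beats = data.frame(beat = seq_len(spec$n_beats), stim_time = stim,
                         takeoff_time = stim, apd50 = apd50, apd90 = apd90),
      dads = data.frame(time = dad_t, amplitude = dad_a)
    )
    trace
  })
}

#' Generate a synthetic fluorescence trace with known ground truth
#'
#' Stimulated transients rise linearly over `time_to_peak` and decay
#' mono-exponentially with `decay_tau` (so the true half-decay time is
#' `decay_tau * log(2)`). A caffeine pulse is modeled as one large transient
#' with its own (NCX-limited) decay constant; Ca2+ waves at rest are
#' raised-cosine excursions. The raw signal is
#' `background + f0 * (1 + dF/F0) + noise`.
#'
#' @param stim_rate field-stimulation rate (Hz); 0 for a resting trace.
#' @param transient_amplitude stimulated-transient amplitude (dF/F0).
#' @param decay_tau transient decay constant (ms).
#' @param n_transients number of stimulated transients.
#' @param caffeine_time optional caffeine-pulse onset (ms).
#' @param caffeine_amplitude,caffeine_tau caffeine transient amplitude
#'   (dF/F0) and decay constant (ms).
#' @param wave_events optional `data.frame(time, amplitude)` of resting
#'   events (peak time ms, amplitude dF/F0); width set by `wave_width`.
#' @param wave_width full base width of wave events (ms).
#' @param noise_sd additive Gaussian noise SD (raw fluorescence units).
#' @param sampling_rate sampling rate (Hz).
#' @param baseline_f0 diastolic fluorescence F0 (raw units).
#' @param background background luminescence (raw units).
#' @param time_to_peak transient rise time (ms).
#' @param duration total duration (ms); computed from the events if `NULL`.
#' @param stim_start time of the first stimulus (ms).
#' @param seed integer RNG seed.
#' @return a `FluorescenceTrace` with a `ground_truth` attribute.
#' @export
gen_ca_trace <- function(stim_rate = 1, transient_amplitude = 1,
                         decay_tau = 200, n_transients = 10L,
                         caffeine_time = NULL, caffeine_amplitude = 0.8,
                         caffeine_tau = 800, wave_events = NULL,
                         wave_width = 300, noise_sd = 0, sampling_rate = 2000,
                         baseline_f0 = 100, background = 10,
                         time_to_peak = 10, duration = NULL, stim_start = 500,
                         seed = 1L) {
  if (stim_rate < 0) stop("stim_rate must be 0 (resting) or positive")
  if (transient_amplitude < 0) stop("transient_amplitude must be >= 0")
  if (decay_tau <= 0) stop("decay_tau must be positive")
  if (caffeine_tau <= 0) stop("caffeine_tau must be positive")
  if (!is.null(wave_events) && any(wave_events$amplitude < 0))
    stop("wave amplitudes must be >= 0")

  with_seed(seed, {
    stim <- if (stim_rate > 0)
      stim_start + (seq_len(n_transients) - 1) * 1000 / stim_rate
    else numeric(0)
    cand <- c(2000,
              if (length(stim)) max(stim) + max(5 * decay_tau, 1000 / max(stim_rate, 1e-9)),
              if (!is.null(caffeine_time)) caffeine_time + 5 * caffeine_tau,
              if (!is.null(wave_events)) max(wave_events$time) + wave_width)
    if (is.null(duration)) duration <- max(cand)
    n <- round(duration * sampling_rate / 1000) + 1L
    t <- (seq_len(n) - 1) / sampling_rate * 1000
    dff <- numeric(n)

    add_exp_event <- function(dff, onset, amp, ttp, tau) {
      rel <- t - onset
      ris <- rel >= 0 & rel < ttp
      dff[ris] <- dff[ris] + amp * rel[ris] / ttp
      dec <- rel >= ttp
      dff[dec] <- dff[dec] + amp * exp(-(rel[dec] - ttp) / tau)
      dff
    }
    for (s in stim)
      dff <- add_exp_event(dff, s, transient_amplitude, time_to_peak, decay_tau)
    if (!is.null(caffeine_time))
      dff <- add_exp_event(dff, caffeine_time, caffeine_amplitude, 50, caffeine_tau)
    if (!is.null(wave_events)) {
      for (i in seq_len(nrow(wave_events))) {
        # snap the peak to the sample grid so the true amplitude is attained
        pk <- round(wave_events$time[i] * sampling_rate / 1000) * 1000 / sampling_rate
        rel <- t - (pk - wave_width / 2)
        sel <- rel >= 0 & rel <= wave_width
        dff[sel] <- dff[sel] +
          wave_events$amplitude[i] * 0.5 * (1 - cos(2 * pi * rel[sel] / wave_width))
      }
    }

    f <- background + baseline_f0 * (1 + dff)
    if (noise_sd > 0) f <- f + stats::rnorm(n, 0, noise_sd)

    trace <- fluorescence_trace(f, sampling_rate, background = background,
                                stim_times = if (length(stim)) stim else NULL,
                                caffeine_time = caffeine_time)
    attr(trace, "ground_truth") <- list(
      stim_times = stim, amplitude = transient_amplitude, decay_tau = decay_tau,
      t_half = decay_tau * log(2), time_to_peak = time_to_peak,
      caffeine = if (!is.null(caffeine_time))
        list(time = caffeine_time, amplitude = caffeine_amplitude,
             tau = caffeine_tau) else NULL,
      waves = wave_events, f0 = baseline_f0, background = background,
      noise_sd = noise_sd
    )
    trace
  })
}
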