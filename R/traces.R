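#' Sampled membrane-potential trace
#'
#' Container for a current-clamp voltage recording. Time is implicit:
#' sample `i` is at `(i - 1) / sampling_rate` ms.
#'
#' @param samples numeric vector of membrane potential (mV).
#' @param sampling_rate sampling rate in kHz (samples per ms).
#' @param stimulus_times optional vector of stimulus times (ms).
#' @return an object of class `VoltageTrace`.
#' @export
voltage_trace <- function(samples, sampling_rate, stimulus_times = NULL) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number (kHz)")
  }
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("samples must be finite numeric values (mV)")
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = sampling_rate,
         stimulus_times = if (is.null(stimulus_times)) NULL else as.numeric(stimulus_times)),
    class = "VoltageTrace"
  )
}

#' Sampled fluorescence trace
#'
#' Container for a Fluo-4 fluorescence recording with acquisition metadata.
#'
#' @param samples numeric vector of fluorescence (arbitrary units, or F/F0
#'   after [normalize_f()]).
#' @param sampling_rate sampling rate in Hz.
#' @param background background luminescence to subtract before F/F0
#'   normalization (same units as `samples`).
#' @param stim_times optional field-stimulus times (ms).
#' @param caffeine_time optional caffeine-pulse time (ms).
#' @return an object of class `FluorescenceTrace`.
#' @export
fluorescence_trace <- function(samples, sampling_rate, background = 0,
                               stim_times = NULL, caffeine_time = NULL) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number (Hz)")
  }
  if (background < 0) stop("background must be >= 0")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = sampling_rate,
         background = background,
         stim_times = if (is.null(stim_times)) NULL else as.numeric(stim_times),
         caffeine_time = caffeine_time),
    class = "FluorescenceTrace"
  )
}

#' Sample times of a trace in milliseconds
#'
#' @param trace a `VoltageTrace` or `FluorescenceTrace`.
#' @return numeric vector of times (ms), starting at 0.
#' @export
trace_times <- function(trace) {
  n <- length(trace$samples)
  if (inherits(trace, "VoltageTrace")) {
    (seq_len(n) - 1) / trace$sampling_rate
  } else if (inherits(trace, "FluorescenceTrace")) {
    (seq_len(n) - 1) / trace$sampling_rate * 1000
  } else {
    stop("not a trace object")
  }
}

#' Ground truth attached to a synthetic object
#'
#' @param x an object produced by one of the generators.
#' @return the generator's ground-truth list, or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' @export
print.VoltageTrace <- function(x, ...) {
  dur <- (length(x$samples) - 1) / x$sampling_rate
  cat(sprintf("<VoltageTrace> %d samples @ %g kHz (%.1f ms), range [%.1f, %.1f] mV\n",
              length(x$samples), x$sampling_rate, dur,
              min(x$samples), max(x$samples)))
  if (!is.null(x$stimulus_times))
    cat(sprintf("  %d stimulus annotations\n", length(x$stimulus_times)))
  invisible(x)
}

#' @export
print.FluorescenceTrace <- function(x, ...) {
  dur <- (length(x$samples) - 1) / x$sampling_rate
  cat(sprintf("<FluorescenceTrace> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate, dur))
  if (isTRUE(attr(x, "normalized"))) cat("  normalized (F/F0)\n")
  if (!is.null(x$stim_times) && length(x$stim_times))
    cat(sprintf("  %d stimuli; ", length(x$stim_times)))
  if (!is.null(x$caffeine_time))
    cat(sprintf("  caffeine at %g ms\n", x$caffeine_time))
  invisible(x)
}

#' @export
plot.VoltageTrace <- function(x, ...) {
  graphics::plot(trace_times(x), x$samples, type = "l",
                 xlab = "time (ms)", ylab = "Vm (mV)", ...)
  invisible(x)
}

#' @export
plot.FluorescenceTrace <- function(x, ...) {
  ylab <- if (isTRUE(attr(x, "normalized"))) "F/F0" else "F (a.u.)"
  graphics::plot(trace_times(x), x$samples, type = "l",
                 xlab = "time (ms)", ylab = ylab, ...)
  invisible(x)
}
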