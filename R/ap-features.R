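#' Segment a voltage trace into single action potentials
#'
#' Beats are delimited at take-off (the time of maximal upstroke velocity).
#' When stimulus annotations are available the take-off is located within a
#' short window after each stimulus; otherwise candidate upstrokes are found
#' where dV/dt exceeds `dvdt_threshold`, grouped with a refractory gap. Each
#' segment spans its take-off to the next take-off (or the trace end) and
#' additionally carries up to `pre_window` ms of preceding diastole so that
#' the diastolic potential can be measured.
#'
#' @param trace a `VoltageTrace`.
#' @param dvdt_threshold upstroke-detection threshold (V/s).
#' @param refractory minimum separation between take-offs (ms).
#' @param pre_window diastolic context retained before take-off (ms).
#' @param stim_window search window after a stimulus annotation (ms).
#' @return an `ap_segments` list (possibly empty, with a warning for a
#'   flat trace); each element has `t`, `v`, `takeoff_idx`, `takeoff_time`
#'   and `sampling_rate`.
#' @export
segment_aps <- function(trace, dvdt_threshold = 10, refractory = 100,
                        pre_window = 55, stim_window = 20) {
  stopifnot(inherits(trace, "VoltageTrace"))
  v <- trace$samples
  fs <- trace$sampling_rate
  t <- trace_times(trace)
  n <- length(v)
  dvdt <- c(NA_real_, diff(v)) * fs  # mV/ms == V/s
  if (max(dvdt, na.rm = TRUE) < dvdt_threshold) {
    warning("no action potentials detected (flat or sub-threshold trace)")
    return(structure(list(), class = "ap_segments"))
  }
  # earliest index reaching the maximal slope (within numerical tolerance),
  # so flat-topped upstrokes yield a deterministic take-off
  first_max <- function(ii) {
    mx <- max(dvdt[ii])
    ii[which(dvdt[ii] >= mx - 1e-9 * abs(mx))[1L]]
  }
  if (!is.null(trace$stimulus_times) && length(trace$stimulus_times)) {
    takeoffs <- vapply(trace$stimulus_times, function(s) {
      i0 <- findInterval(s, t) + 1L
      i1 <- min(n, findInterval(s + stim_window, t))
      if (i0 > i1) return(NA_integer_)
      as.integer(first_max(i0:i1))
    }, 1L)
    takeoffs <- takeoffs[!is.na(takeoffs)]
  } else {
    idx <- which(!is.na(dvdt) & dvdt > dvdt_threshold)
    grp <- cumsum(c(TRUE, diff(t[idx]) > refractory))
    takeoffs <- vapply(split(idx, grp), first_max, 1L)
    takeoffs <- sort(unname(takeoffs))
  }
  if (!length(takeoffs)) {
    warning("no action potentials detected")
    return(structure(list(), class = "ap_segments"))
  }
  bounds <- c(takeoffs, n + 1L)
  segs <- lapply(seq_along(takeoffs), function(i) {
    start <- takeoffs[i]
    end <- bounds[i + 1L] - 1L
    pre_start <- max(1L, start - as.integer(round(pre_window * fs)))
    structure(
      list(t = t[pre_start:end], v = v[pre_start:end],
           takeoff_idx = start - pre_start + 1L,
           takeoff_time = t[start], sampling_rate = fs),
      class = "ap_segment"
    )
  })
  structure(segs, class = "ap_segments")
}

#' @export
print.ap_segments <- function(x, ...) {
  cat(sprintf("<ap_segments> %d beat(s)\n", length(x)))
  invisible(x)
}

#' Action-potential features of one beat
#'
#' APD at repolarization fraction `x` is the time from take-off (the time
#' of maximal dV/dt) to the first interpolated crossing of
#' `peak - x * (peak - E_diast)`. The diastolic potential `E_diast` is the
#' mean over a window ending shortly before take-off (falling back to the
#' late-diastolic tail of the segment for a first beat without context). A
#' beat that never repolarizes to a requested level yields `NA` for that
#' APD rather than an extrapolation.
#'
#' @param segment an `ap_segment` from [segment_aps()].
#' @param repolarization_fractions repolarization levels (defaults 0.5, 0.9).
#' @param ediast_window,ediast_gap diastolic averaging window and its gap
#'   before take-off (ms).
#' @param smooth_window moving-average window (samples) applied before
#'   differentiation; 0 disables smoothing (appropriate for clean data).
#' @return an `APFeatures` list: `apd50`, `apd90` (or the requested
#'   fractions, in `apd`), `e_diast`, `dvdt_max`, `peak`, `take_off_time`.
#' @export
ap_features <- function(segment, repolarization_fractions = c(0.5, 0.9),
                        ediast_window = 50, ediast_gap = 5,
                        smooth_window = 0) {
  stopifnot(inherits(segment, "ap_segment"))
  t <- segment$t; v <- segment$v
  fs <- segment$sampling_rate
  n <- length(v)
  ko <- segment$takeoff_idx
  vs <- if (smooth_window > 1) moving_average(v, smooth_window) else v
  dvdt <- c(NA_real_, diff(vs)) * fs
  up_end <- min(n, ko + as.integer(round(10 * fs)))
  dvdt_max <- max(dvdt[ko:up_end], na.rm = TRUE)
  takeoff_time <- segment$takeoff_time

  pre_sel <- t >= takeoff_time - ediast_gap - ediast_window &
             t <= takeoff_time - ediast_gap
  e_diast <- if (sum(pre_sel) >= 3) {
    mean(v[pre_sel])
  } else {
    # no pre-beat context: use the late-diastolic tail of the segment
    tail_sel <- seq.int(max(1L, n - as.integer(round(0.1 * n))), n)
    stats::median(v[tail_sel])
  }

  peak_idx <- ko - 1L + which.max(v[ko:n])
  peak <- v[peak_idx]
  apd <- vapply(repolarization_fractions, function(x) {
    level <- peak - x * (peak - e_diast)
    tc <- first_cross_down(t, v, level, from = peak_idx)
    if (is.na(tc)) NA_real_ else tc - takeoff_time
  }, 0)
  names(apd) <- paste0("apd", round(100 * repolarization_fractions))

  structure(
    list(apd50 = unname(apd["apd50"]), apd90 = unname(apd["apd90"]),
         apd = apd, e_diast = e_diast, dvdt_max = dvdt_max, peak = peak,
         take_off_time = takeoff_time,
         missing = names(apd)[is.na(apd)]),
    class = "APFeatures"
  )
}

#' @export
print.APFeatures <- function(x, ...) {
  cat(sprintf("<APFeatures> APD50 %.1f ms, APD90 %.1f ms, Ediast %.1f mV, dV/dt_max %.0f V/s, peak %.1f mV\n",
              x$apd50, x$apd90, x$e_diast, x$dvdt_max, x$peak))
  invisible(x)
}

#' Per-beat feature table for a segmented trace
#'
#' @param segments an `ap_segments` object.
#' @param ... passed to [ap_features()].
#' @return a data.frame with one row per beat.
#' @export
ap_features_table <- function(segments, ...) {
  rows <- lapply(seq_along(segments), function(i) {
    f <- ap_features(segments[[i]], ...)
    data.frame(beat = i, take_off_time = f$take_off_time, apd50 = f$apd50,
               apd90 = f$apd90, e_diast = f$e_diast, dvdt_max = f$dvdt_max,
               peak = f$peak)
  })
  do.call(rbind, rows) %||% data.frame()
}

#' Detect delayed afterdepolarizations (DADs)
#'
#' DADs are diastolic depolarizing deflections with baseline-to-peak
#' amplitude of at least `min_amplitude` (1 mV by definition). The diastole
#' of each beat runs from APD90 completion (plus a margin) to just before
#' the next take-off. Candidate deflections must exceed the local diastolic
#' baseline (median) by `candidate_delta` on a lightly smoothed copy for at
#' least `min_duration` ms; their amplitude is measured on the raw trace so
#' that the 1 mV rule is applied exactly.
#'
#' @param trace a `VoltageTrace`.
#' @param segments optional pre-computed [segment_aps()] result.
#' @param min_amplitude amplitude rule (mV); events with amplitude >= this
#'   value (inclusive) are reported.
#' @param candidate_delta sustained-excursion threshold above baseline (mV).
#' @param min_duration minimum excursion duration (ms).
#' @param merge_gap gap below threshold merged into one event (ms).
#' @param smooth_ms moving-average width for candidate detection (ms).
#' @param post_apd_margin,pre_takeoff_margin margins excluded after APD90
#'   completion and before the next take-off (ms).
#' @return a data.frame of `DADEvent`s (`time`, `amplitude`), with
#'   attribute `has_dads` (the per-cell flag).
#' @export
detect_dads <- function(trace, segments = NULL, min_amplitude = 1,
                        candidate_delta = 0.5, min_duration = 5,
                        merge_gap = 10, smooth_ms = 2,
                        post_apd_margin = 20, pre_takeoff_margin = 20) {
  if (is.null(segments)) segments <- segment_aps(trace)
  fs <- trace$sampling_rate
  out_t <- numeric(0); out_a <- numeric(0)
  for (seg in segments) {
    f <- ap_features(seg)
    if (is.na(f$apd90)) next
    dia0 <- seg$takeoff_time + f$apd90 + post_apd_margin
    dia1 <- max(seg$t) - pre_takeoff_margin
    sel <- seg$t >= dia0 & seg$t <= dia1
    if (sum(sel) < 10) next
    vv <- seg$v[sel]; tt <- seg$t[sel]
    base <- stats::median(vv)
    sm <- moving_average(vv, max(1L, as.integer(round(smooth_ms * fs))))
    runs <- logical_runs(sm > base + candidate_delta,
                         min_len = max(1L, as.integer(round(min_duration * fs))),
                         merge_gap = as.integer(round(merge_gap * fs)))
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      # a run already above threshold at the window start is the tail of
      # repolarization, not a diastolic deflection
      if (runs$start[r] == 1L) next
      ii <- runs$start[r]:runs$end[r]
      amp <- max(vv[ii]) - base
      if (amp >= min_amplitude - 1e-9) {
        out_t <- c(out_t, tt[ii[which.max(vv[ii])]])
        out_a <- c(out_a, amp)
      }
    }
  }
  res <- data.frame(time = out_t, amplitude = out_a)
  attr(res, "has_dads") <- nrow(res) > 0
  res
}

#' Detect early afterdepolarizations (EADs)
#'
#' Flags secondary depolarizations during repolarization: places between
#' the AP peak and the APD90 crossing where the potential turns upward
#' again and rises by at least `min_deflection` from a local minimum. The
#' amplitude threshold is a configurable setting, not a literature-fixed
#' rule.
#'
#' @param segment an `ap_segment`.
#' @param min_deflection minimum rise from a local minimum (mV).
#' @param smooth_window optional moving-average window (samples).
#' @return numeric vector of event times (ms); empty if none.
#' @export
detect_eads <- function(segment, min_deflection = 1, smooth_window = 0) {
  f <- ap_features(segment)
  t <- segment$t; v <- segment$v
  if (smooth_window > 1) v <- moving_average(v, smooth_window)
  peak_idx <- segment$takeoff_idx - 1L +
    which.max(segment$v[segment$takeoff_idx:length(v)])
  end_t <- if (!is.na(f$apd90)) f$take_off_time + f$apd90 else max(t)
  sel <- which(t >= t[peak_idx] & t <= end_t)
  if (length(sel) < 3) return(numeric(0))
  vv <- v[sel]; tt <- t[sel]
  events <- numeric(0)
  run_min <- vv[1L]
  run_max <- -Inf
  armed <- TRUE
  for (j in 2:length(vv)) {
    if (armed) {
      if (vv[j] < run_min) run_min <- vv[j]
      if (vv[j] - run_min >= min_deflection) {
        events <- c(events, tt[j])
        armed <- FALSE       # hysteresis: one event per rise
        run_max <- vv[j]
      }
    } else {
      if (vv[j] > run_max) run_max <- vv[j]
      if (run_max - vv[j] >= min_deflection) {
        armed <- TRUE
        run_min <- vv[j]
      }
    }
  }
  events
}

#' Short-term variability (STV) of repolarization
#'
#' The mean orthogonal deviation of consecutive APD pairs from the Poincare
#' identity line: `STV = sum(|APD[n+1] - APD[n]|) / (n_beats * sqrt(2))`,
#' conventionally computed over 30 consecutive steady-state beats. A
#' denominator of `n_beats * 2` is available as an alternative convention
#' (`denominator = "two"`), since both appear in the applied literature.
#'
#' @param apd_sequence numeric vector of consecutive APD values (ms).
#' @param denominator `"sqrt2"` (default) or `"two"`.
#' @return a `BVRResult`: `stv` (ms), `poincare_pairs`
#'   (`data.frame(apd_n, apd_n1)`), `n_beats`.
#' @export
stv <- function(apd_sequence, denominator = c("sqrt2", "two")) {
  denominator <- match.arg(denominator)
  apd_sequence <- as.numeric(apd_sequence)
  n <- length(apd_sequence)
  if (n < 2L) stop("STV requires at least 2 APD values")
  if (anyNA(apd_sequence)) stop("APD sequence contains missing values")
  s <- sum(abs(diff(apd_sequence)))
  den <- if (denominator == "sqrt2") n * sqrt(2) else n * 2
  structure(
    list(stv = s / den,
         poincare_pairs = data.frame(apd_n = apd_sequence[-n],
                                     apd_n1 = apd_sequence[-1L]),
         n_beats = n, denominator = denominator),
    class = "BVRResult"
  )
}

#' @export
print.BVRResult <- function(x, ...) {
  cat(sprintf("<BVRResult> STV %.3f ms over %d beats (denominator n*%s)\n",
              x$stv, x$n_beats, if (x$denominator == "sqrt2") "sqrt(2)" else "2"))
  invisible(x)
}

#' Regression of STV on APD90 across cells
#'
#' Ordinary least squares of per-cell STV on per-cell APD90; the slope of
#' this relation indexes how much repolarization variability scales with
#' APD prolongation across experimental groups.
#'
#' @param cells a data.frame with columns `apd90` and `stv` (one row per
#'   cell).
#' @return list with `slope`, `intercept`, `r`, and the `lm` fit.
#' @export
stv_apd_regression <- function(cells) {
  if (!all(c("apd90", "stv") %in% names(cells)))
    stop("cells must have columns 'apd90' and 'stv'")
  if (nrow(cells) < 2L)
    stop("at least 2 cells are required (3+ for a meaningful fit)")
  if (stats::sd(cells$apd90) == 0)
    stop("degenerate input: all APD90 values are equal")
  fit <- stats::lm(stv ~ apd90, data = cells)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(cells$apd90, cells$stv),
       fit = fit)
}
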