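#' Normalize a fluorescence trace to F/F0
#'
#' Subtracts background luminescence and divides by the diastolic reference
#' fluorescence F0, itself background-subtracted:
#' `(F - bg) / (F0 - bg)`. For paced traces F0 is the median over the last
#' `diastolic_fraction` of each pre-stimulus cycle (pre-caffeine only); for
#' resting traces it is the median after two rounds of excluding samples
#' more than 3 robust SDs above the median (so sparse events do not bias
#' the baseline). The normalization is invariant to affine gain/offset
#' changes of the raw signal given a correct background.
#'
#' @param trace a `FluorescenceTrace` (raw units).
#' @param f0 optional explicit diastolic fluorescence (raw units).
#' @param diastolic_fraction fraction of each cycle treated as diastole.
#' @return a normalized `FluorescenceTrace` (diastolic level approximately
#'   1) with attributes `f0` and `normalized`.
#' @export
normalize_f <- function(trace, f0 = NULL, diastolic_fraction = 0.2) {
  stopifnot(inherits(trace, "FluorescenceTrace"))
  bg <- trace$background %||% 0
  raw <- trace$samples
  t <- trace_times(trace)
  if (is.null(f0)) {
    st <- trace$stim_times
    cutoff <- trace$caffeine_time %||% Inf
    if (!is.null(st) && length(st) >= 1L) {
      st <- st[st < cutoff]
      gaps <- if (length(st) >= 2L) c(diff(st)[1L], diff(st)) else rep(500, length(st))
      sel <- rep(FALSE, length(raw))
      for (i in seq_along(st)) {
        w0 <- st[i] - diastolic_fraction * gaps[i]
        sel <- sel | (t >= w0 & t < st[i] - 1)
      }
      if (!any(sel)) sel <- t < st[1L]
      f0 <- stats::median(raw[sel])
    } else {
      x <- raw[t < cutoff]
      for (k in 1:2) {
        m <- stats::median(x)
        s <- stats::mad(x)
        if (s > 0) x <- x[x <= m + 3 * s]
      }
      f0 <- stats::median(x)
    }
  }
  if (bg >= f0)
    stop("background (", bg, ") is not below diastolic fluorescence (", f0,
         "): non-physical")
  out <- trace
  out$samples <- (raw - bg) / (f0 - bg)
  out$background <- 0
  attr(out, "f0") <- f0
  attr(out, "normalized") <- TRUE
  attr(out, "ground_truth") <- attr(trace, "ground_truth")
  out
}

#' Features of stimulated Ca2+ transients
#'
#' For each stimulus: amplitude is peak minus the pre-stimulus diastolic
#' level (dF/F0), `t_half` is the interpolated time from the peak to 50%
#' decay of the amplitude (flagged `NA` when the transient has not decayed
#' below 50% before the next stimulus), `time_to_peak` from stimulus to
#' peak, and (optionally) a log-linear mono-exponential decay constant.
#' The steady-state summary averages the last `steady_k` transients.
#'
#' @param trace a normalized `FluorescenceTrace` (see [normalize_f()]).
#' @param stim_times stimulus times (ms); defaults to the trace metadata.
#' @param steady_k transients averaged for the steady-state summary.
#' @param pre_window,pre_gap pre-stimulus averaging window and gap (ms).
#' @param fit_tau also fit a mono-exponential decay constant per transient.
#' @param min_amplitude transients below this dF/F0 are kept in the table
#'   but their kinetic features are flagged missing.
#' @return a data.frame (one row per transient: `stim_time`, `amplitude`,
#'   `time_to_peak`, `t_half`, `decay_tau`) with attribute `steady_state`.
#' @export
transient_features <- function(trace, stim_times = NULL, steady_k = 5L,
                               pre_window = 20, pre_gap = 2, fit_tau = TRUE,
                               min_amplitude = 0.02) {
  st <- stim_times %||% trace$stim_times
  if (is.null(st) || !length(st)) stop("no stimulated transients: stim_times required")
  y <- trace$samples
  t <- trace_times(trace)
  end_cap <- min(trace$caffeine_time %||% Inf, max(t))
  ends <- c(st[-1L], end_cap)
  rows <- lapply(seq_along(st), function(i) {
    s <- st[i]
    sel <- which(t >= s & t < ends[i])
    pre_sel <- which(t >= s - pre_window & t <= s - pre_gap)
    pre <- if (length(pre_sel) >= 2L) mean(y[pre_sel]) else y[sel[1L]]
    pk_rel <- which.max(y[sel])
    pk_idx <- sel[pk_rel]
    amplitude <- y[pk_idx] - pre
    if (amplitude < min_amplitude) {
      return(data.frame(stim_time = s, amplitude = amplitude,
                        time_to_peak = NA_real_, t_half = NA_real_,
                        decay_tau = NA_real_))
    }
    ttp <- t[pk_idx] - s
    half_level <- pre + amplitude / 2
    tc <- first_cross_down(t[sel], y[sel], half_level, from = pk_rel)
    t_half <- if (is.na(tc)) NA_real_ else tc - t[pk_idx]
    tau <- NA_real_
    if (fit_tau) {
      dec <- sel[sel >= pk_idx]
      z <- y[dec] - pre
      keep <- z > 0.05 * amplitude
      # use the contiguous decaying stretch from the peak
      stop_at <- which(!keep)[1L]
      if (!is.na(stop_at) && stop_at > 1L) keep[stop_at:length(keep)] <- FALSE
      if (sum(keep) >= 4L) {
        fit <- stats::lm(log(z[keep]) ~ t[dec][keep])
        sl <- unname(stats::coef(fit)[2L])
        if (is.finite(sl) && sl < 0) tau <- -1 / sl
      }
    }
    data.frame(stim_time = s, amplitude = amplitude, time_to_peak = ttp,
               t_half = t_half, decay_tau = tau)
  })
  res <- do.call(rbind, rows)
  k <- min(steady_k, nrow(res))
  tail_rows <- res[seq.int(nrow(res) - k + 1L, nrow(res)), , drop = FALSE]
  attr(res, "steady_state") <- list(
    amplitude = mean(tail_rows$amplitude),
    t_half = mean(tail_rows$t_half, na.rm = TRUE),
    time_to_peak = mean(tail_rows$time_to_peak, na.rm = TRUE),
    n = k
  )
  res
}

#' Caffeine-pulse analysis: SR content and NCX-limited decay
#'
#' The amplitude of the caffeine-evoked transient (peak minus pre-caffeine
#' baseline, dF/F0) estimates the SR Ca2+ content; the decay constant of a
#' least-squares mono-exponential fit `A * exp(-t / tau) + C` to the
#' post-peak segment estimates Na/Ca-exchanger extrusion. The fit window
#' runs from the transient peak over `fit_fraction` of the remaining trace.
#' A segment that does not decay aborts with an error rather than returning
#' a silent fallback.
#'
#' @param trace a normalized `FluorescenceTrace`.
#' @param caffeine_time caffeine onset (ms); defaults to trace metadata.
#' @param baseline_window pre-caffeine baseline window (ms).
#' @param search_window window after onset searched for the peak (ms).
#' @param fit_fraction fraction of the available post-peak samples fitted.
#' @return a `CaffeineResult`: `casr` (dF/F0), `ncx_tau` (ms), `fit`.
#' @export
caffeine_analysis <- function(trace, caffeine_time = NULL,
                              baseline_window = 200, search_window = 3000,
                              fit_fraction = 0.95) {
  ct <- caffeine_time %||% trace$caffeine_time
  if (is.null(ct)) stop("caffeine_time is required")
  y <- trace$samples
  t <- trace_times(trace)
  if (ct <= min(t) || ct >= max(t)) stop("caffeine_time outside the trace")
  base_sel <- which(t >= ct - baseline_window & t <= ct - 5)
  base <- if (length(base_sel) >= 2L) mean(y[base_sel]) else y[which(t >= ct)[1L]]
  sel <- which(t >= ct & t <= ct + search_window)
  pk_rel <- which.max(y[sel])
  pk_idx <- sel[pk_rel]
  casr <- y[pk_idx] - base
  if (casr <= 0) stop("no caffeine transient found after caffeine_time")

  n <- length(y)
  dec_idx <- pk_idx:(pk_idx + floor(fit_fraction * (n - pk_idx)))
  td <- t[dec_idx] - t[pk_idx]
  yd <- y[dec_idx]
  if (yd[length(yd)] - base > 0.7 * casr)
    stop("caffeine transient does not decay over the fit window; mono-exponential fit aborted")
  z <- yd - base
  pos <- z > 0.05 * casr
  tau0 <- 500
  if (sum(pos) >= 4L) {
    sl <- unname(stats::coef(stats::lm(log(z[pos]) ~ td[pos]))[2L])
    if (is.finite(sl) && sl < 0) tau0 <- -1 / sl
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(yd ~ A * exp(-td / tau) + C,
                      start = list(A = casr, tau = tau0, C = base),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("mono-exponential fit failed: ", conditionMessage(e)))
  co <- stats::coef(fit)
  if (co[["tau"]] <= 0) stop("mono-exponential fit failed: non-positive tau")
  structure(list(casr = casr, ncx_tau = unname(co[["tau"]]), fit = fit,
                 baseline = base),
            class = "CaffeineResult")
}

#' @export
print.CaffeineResult <- function(x, ...) {
  cat(sprintf("<CaffeineResult> CaSR %.3f dF/F0, NCX tau %.1f ms\n",
              x$casr, x$ncx_tau))
  invisible(x)
}

#' Detect resting SR-instability events (Ca2+ waves, resting transients)
#'
#' On an unstimulated normalized trace, the resting level `F_rest` and its
#' SD are estimated with two rounds of excluding samples more than 3 SD
#' above the mean (events would otherwise inflate the naive SD). A Ca2+
#' wave is an excursion exceeding `sd_cutoff` resting SDs for at least
#' `min_run` consecutive samples (the run-length requirement suppresses
#' single-sample threshold touches). Events whose dF/F0 amplitude also
#' reaches the resting-transient criterion — 50% of the cell's paced CaT
#' amplitude when available, else `resting_cat_min` — are labeled
#' `resting_transient`.
#'
#' @param trace a normalized resting `FluorescenceTrace`.
#' @param sd_cutoff wave amplitude cutoff in resting SDs (default 3).
#' @param min_run consecutive supra-threshold samples required.
#' @param merge_gap sub-threshold gap merged into one event (ms).
#' @param resting_cat_min resting-transient dF/F0 criterion when no paced
#'   amplitude is supplied.
#' @param paced_amplitude mean stimulated CaT amplitude of the cell
#'   (dF/F0), if known.
#' @param f_rest,f_rest_sd optional externally supplied resting level and
#'   SD (bypass the iterative estimate).
#' @return data.frame of `RestingEvent`s (`kind`, `time`, `amplitude_sd`,
#'   `amplitude_dff`), with attributes `f_rest`, `f_rest_sd`, `has_waves`,
#'   `has_resting_transients`.
#' @export
detect_resting_events <- function(trace, sd_cutoff = 3, min_run = 3L,
                                  merge_gap = 50, resting_cat_min = 0.5,
                                  paced_amplitude = NULL,
                                  f_rest = NULL, f_rest_sd = NULL) {
  y <- trace$samples
  t <- trace_times(trace)
  if (is.null(f_rest) || is.null(f_rest_sd)) {
    x <- y
    for (k in 1:2) {
      m <- mean(x); s <- stats::sd(x)
      if (!is.finite(s) || s == 0) break
      x <- x[x <= m + 3 * s]
    }
    f_rest <- f_rest %||% mean(x)
    f_rest_sd <- f_rest_sd %||% stats::sd(x)
  }
  empty <- data.frame(kind = character(0), time = numeric(0),
                      amplitude_sd = numeric(0), amplitude_dff = numeric(0))
  if (!is.finite(f_rest_sd) || f_rest_sd <= 0) {
    attr(empty, "f_rest") <- f_rest
    attr(empty, "f_rest_sd") <- f_rest_sd
    attr(empty, "has_waves") <- FALSE
    attr(empty, "has_resting_transients") <- FALSE
    return(empty)
  }
  dev <- y - f_rest
  rate_ms <- trace$sampling_rate / 1000  # samples per ms
  runs <- logical_runs(dev > sd_cutoff * f_rest_sd,
                       min_len = as.integer(min_run),
                       merge_gap = as.integer(round(merge_gap * rate_ms)))
  if (!nrow(runs)) {
    res <- empty
  } else {
    amp <- vapply(seq_len(nrow(runs)),
                  function(r) max(dev[runs$start[r]:runs$end[r]]), 0)
    tim <- vapply(seq_len(nrow(runs)), function(r) {
      ii <- runs$start[r]:runs$end[r]
      t[ii[which.max(dev[ii])]]
    }, 0)
    rt_thr <- if (!is.null(paced_amplitude)) 0.5 * paced_amplitude else resting_cat_min
    res <- data.frame(
      kind = ifelse(amp >= rt_thr, "resting_transient", "wave"),
      time = tim, amplitude_sd = amp / f_rest_sd, amplitude_dff = amp)
  }
  attr(res, "f_rest") <- f_rest
  attr(res, "f_rest_sd") <- f_rest_sd
  attr(res, "has_waves") <- any(res$kind == "wave")
  attr(res, "has_resting_transients") <- any(res$kind == "resting_transient")
  res
}

#' Normalize treated-group measurements to control, by cycle length
#'
#' For each pacing cycle length present in both tables, the ratio of the
#' treated mean to the control mean is computed, with the standard error
#' propagated as
#' `ratio * sqrt((SE_t / m_t)^2 + (SE_c / m_c)^2)`.
#'
#' @param treated,ctrl data.frames with a grouping column (`by`) and a
#'   measurement column (`value`).
#' @param by name of the cycle-length (or rate) column.
#' @param value name of the measurement column.
#' @return data.frame with one row per cycle length: `ratio`, `se`,
#'   `n_treated`, `n_ctrl`.
#' @export
normalize_to_ctrl <- function(treated, ctrl, by = "cycle_length",
                              value = "value") {
  for (d in list(treated, ctrl)) {
    if (!all(c(by, value) %in% names(d)))
      stop("tables must have columns '", by, "' and '", value, "'")
  }
  agg <- function(d) {
    sp <- split(d[[value]], d[[by]])
    data.frame(level = names(sp),
               n = lengths(sp),
               mean = vapply(sp, mean, 0),
               se = vapply(sp, function(x) stats::sd(x) / sqrt(length(x)), 0),
               stringsAsFactors = FALSE)
  }
  at <- agg(treated); ac <- agg(ctrl)
  missing_lv <- setdiff(at$level, ac$level)
  if (length(missing_lv))
    stop("no control values for cycle length(s): ",
         paste(missing_lv, collapse = ", "))
  ac <- ac[match(at$level, ac$level), ]
  ratio <- at$mean / ac$mean
  se <- abs(ratio) * sqrt((at$se / at$mean)^2 + (ac$se / ac$mean)^2)
  out <- data.frame(level = at$level, ratio = ratio, se = se,
                    n_treated = at$n, n_ctrl = ac$n,
                    stringsAsFactors = FALSE)
  names(out)[1L] <- by
  rownames(out) <- NULL
  out
}
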