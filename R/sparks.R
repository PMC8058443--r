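# Per-column (spatial pixel) baseline statistics of an xt image, with
# iterative exclusion of supra-threshold samples so sparks do not inflate
# the baseline mean or SD.
col_baseline <- function(m, cri = 3.8, iterations = 3L) {
  nl <- nrow(m)
  mu <- colMeans(m)
  sg <- sqrt(colSums(sweep(m, 2L, mu)^2) / (nl - 1L))
  for (it in seq_len(iterations)) {
    thr <- matrix(mu + cri * sg, nl, ncol(m), byrow = TRUE)
    keep <- m <= thr
    nk <- colSums(keep)
    nk[nk == 0L] <- 1L
    mu <- colSums(m * keep) / nk
    dev2 <- (m - matrix(mu, nl, ncol(m), byrow = TRUE))^2
    sg <- sqrt(colSums(dev2 * keep) / pmax(nk - 1L, 1L))
  }
  list(mu = mu, sigma = sg)
}

#' Detect Ca2+ spark candidate regions on a line-scan image
#'
#' Deterministic two-pass detection in the SparkMaster tradition:
#' (1) per spatial pixel, the baseline mean and SD of the temporal signal
#' are estimated with iterative exclusion of samples above
#' `mu + cri * sigma`; (2) pixels of a lightly smoothed copy (`smooth_k` x
#' `smooth_k` boxcar) exceeding `mu + cri * sigma` are flagged as cores;
#' (3) each core grows to its connected region exceeding
#' `mu + (cri - grow_delta) * sigma`; (4) connected labeling merges
#' overlapping regions; (5) regions smaller than `min_area` pixels are
#' discarded. Detection is fully deterministic.
#'
#' @param image a `LineScanImage`.
#' @param cri detection criterion (default 3.8).
#' @param smooth_k boxcar kernel size (pixels).
#' @param min_area minimum region area (pixels).
#' @param grow_delta criterion reduction for the region-growing pass.
#' @return a `SparkDetection`: `regions` (list of row/col index ranges,
#'   pixel sets and peak positions), the baseline statistics, the
#'   normalized (dF/F0) image, and the smoothed normalized image.
#' @export
detect_sparks <- function(image, cri = 3.8, smooth_k = 3L, min_area = 4L,
                          grow_delta = 1) {
  stopifnot(inherits(image, "LineScanImage"))
  m <- image$matrix
  nl <- nrow(m); np <- ncol(m)
  if (nl <= smooth_k || np <= smooth_k)
    stop("image smaller than the smoothing kernel")
  bl <- col_baseline(m, cri = cri)
  bg <- image$background %||% 0
  denom <- pmax(bl$mu - bg, .Machine$double.eps)
  dff <- sweep(sweep(m, 2L, bl$mu), 2L, denom, "/")

  empty <- structure(
    list(regions = list(), n = 0L, baseline = bl, dff = dff,
         dff_smoothed = NULL, image = image, cri = cri,
         sigma_dff = bl$sigma / denom),
    class = "SparkDetection")
  if (max(bl$sigma) <= 0) {
    warning("zero-variance image: no detections possible")
    return(empty)
  }
  sm <- smooth_boxcar(m, smooth_k)
  mu_m <- matrix(bl$mu, nl, np, byrow = TRUE)
  sg_m <- matrix(bl$sigma, nl, np, byrow = TRUE)
  core <- sm > mu_m + cri * sg_m
  empty$dff_smoothed <- (sm - mu_m) / matrix(denom, nl, np, byrow = TRUE)
  if (!any(core)) return(empty)
  low <- sm > mu_m + (cri - grow_delta) * sg_m
  lab <- EBImage::bwlabel(low * 1L)
  lab <- matrix(as.integer(lab), nl, np)
  ids <- sort(unique(lab[core]))
  ids <- ids[ids > 0L]
  if (!length(ids)) return(empty)
  sizes <- tabulate(lab, nbins = max(lab))
  ids <- ids[sizes[ids] >= min_area]
  if (!length(ids)) return(empty)
  regions <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    vals <- empty$dff_smoothed[px]
    pk <- px[which.max(vals), ]
    list(id = id, pixels = px,
         rows = range(px[, 1L]), cols = range(px[, 2L]),
         peak_row = unname(pk[1L]), peak_col = unname(pk[2L]),
         area = nrow(px))
  })
  empty$regions <- regions
  empty$n <- length(regions)
  empty
}

#' @export
print.SparkDetection <- function(x, ...) {
  cat(sprintf("<SparkDetection> %d region(s) at cri %.1f\n", x$n, x$cri))
  invisible(x)
}

# Half-level crossings of a profile around a peak index, interpolated.
# Returns c(left, right) in the t units, with NA where the profile never
# drops below the level inside the window (edge / partial event).
profile_crossings <- function(t, p, peak_idx, level) {
  left <- NA_real_; right <- NA_real_
  below_l <- which(p[seq_len(peak_idx)] < level)
  if (length(below_l)) {
    i <- max(below_l)
    denom <- p[i + 1L] - p[i]
    frac <- if (denom == 0) 0 else (level - p[i]) / denom
    left <- t[i] + frac * (t[i + 1L] - t[i])
  }
  after <- seq.int(peak_idx, length(p))
  below_r <- which(p[after] < level)
  if (length(below_r)) {
    i <- after[below_r[1L]] - 1L
    denom <- p[i] - p[i + 1L]
    frac <- if (denom == 0) 0 else (p[i] - level) / denom
    right <- t[i] + frac * (t[i + 1L] - t[i])
  }
  c(left, right)
}

#' Parameterize one detected spark
#'
#' The temporal profile is the spatial average of the normalized image over
#' the event's half-maximal width, and the spatial profile the temporal
#' average over its half-maximal duration; because the simulated and
#' physiological kernels are close to separable, averaging rescales but
#' does not reshape the profiles, so FWHM and FDHM are read off by
#' interpolated half-maximum crossings of each profile. Amplitude is the
#' local-baseline-subtracted dF/F0 averaged over a 5-pixel spatial window
#' at the peak line. FW and FD are measured at baseline + 2 local noise
#' SDs (a true zero-crossing is undefined in noise), time-to-peak from the
#' onset (last sub-2SD sample before the peak), and the decay constant by
#' a log-linear mono-exponential fit from the peak. Events whose profiles
#' leave the image before crossing half-maximum are flagged `partial` and
#' excluded from summaries.
#'
#' @param detection a `SparkDetection` from [detect_sparks()].
#' @param region one element of `detection$regions` (or its index).
#' @param pad_ms,pad_um context added around the region when profiling.
#' @param in_focus_min amplitude rule for in-focus sparks (strictly
#'   greater than; default 0.3).
#' @param ember_fdhm FDHM rule for ember classification (strictly greater
#'   than; default 20 ms).
#' @return one-row data.frame (`Spark`): `x_center`, `t_center`,
#'   `amplitude`, `fwhm`, `fdhm`, `fw`, `fd`, `ttp`, `tau_decay`, `mass`,
#'   `in_focus`, `is_ember`, `partial`.
#' @export
spark_params <- function(detection, region, pad_ms = 60, pad_um = 3,
                         in_focus_min = 0.3, ember_fdhm = 20) {
  stopifnot(inherits(detection, "SparkDetection"))
  if (is.numeric(region)) region <- detection$regions[[region]]
  img <- detection$image
  lp <- img$line_period; px <- img$pixel_size
  dff <- detection$dff
  nl <- nrow(dff); np <- ncol(dff)
  ti <- region$peak_row; xi <- region$peak_col
  sigma_dff <- detection$sigma_dff[xi]

  amp_cols <- max(1L, xi - 2L):min(np, xi + 2L)
  amp_fallback <- mean(dff[ti, amp_cols])

  pad_t <- as.integer(round(pad_ms / lp))
  pad_x <- as.integer(round(pad_um / px))
  t0 <- max(1L, region$rows[1L] - pad_t); t1 <- min(nl, region$rows[2L] + pad_t)
  x0 <- max(1L, region$cols[1L] - pad_x); x1 <- min(np, region$cols[2L] + pad_x)
  tt <- (seq.int(t0, t1) - 1) * lp
  xx <- (seq.int(x0, x1) - 1) * px
  t_peak <- (ti - 1) * lp
  x_peak <- (xi - 1) * px

  partial <- FALSE

  # pass 1: temporal profile near the peak column -> half-max duration
  pt1 <- rowMeans(dff[t0:t1, max(1L, xi - 1L):min(np, xi + 1L), drop = FALSE])
  near_t <- which(abs(tt - t_peak) <= 2 * lp)
  pk_t_idx <- near_t[which.max(pt1[near_t])]
  cr <- profile_crossings(tt, pt1, pk_t_idx, max(pt1[pk_t_idx], 1e-12) / 2)
  if (anyNA(cr)) { partial <- TRUE; cr[is.na(cr)] <- range(tt)[is.na(cr)] }
  rows_half <- which(tt >= cr[1L] & tt <= cr[2L])
  if (!length(rows_half)) rows_half <- pk_t_idx

  # spatial profile over the half-max duration -> FWHM
  ps <- colMeans(dff[(t0:t1)[rows_half], x0:x1, drop = FALSE])
  near_x <- which(abs(xx - x_peak) <= 2 * px)
  pk_x_idx <- near_x[which.max(ps[near_x])]
  crx <- profile_crossings(xx, ps, pk_x_idx, max(ps[pk_x_idx], 1e-12) / 2)
  if (anyNA(crx)) { partial <- TRUE; crx[is.na(crx)] <- range(xx)[is.na(crx)] }
  fwhm <- crx[2L] - crx[1L]
  cols_half <- which(xx >= crx[1L] & xx <= crx[2L])
  if (!length(cols_half)) cols_half <- pk_x_idx

  # pass 2: temporal profile over the half-max width -> FDHM, TtP, tau, FD
  pt <- rowMeans(dff[t0:t1, (x0:x1)[cols_half], drop = FALSE])
  pk_t_idx <- near_t[which.max(pt[near_t])]
  peak_prof <- pt[pk_t_idx]
  crt <- profile_crossings(tt, pt, pk_t_idx, max(peak_prof, 1e-12) / 2)
  if (anyNA(crt)) { partial <- TRUE; crt[is.na(crt)] <- range(tt)[is.na(crt)] }
  fdhm <- crt[2L] - crt[1L]

  # Amplitude: peak of the low-noise temporal profile, undone for the known
  # attenuation of averaging a Gaussian spatial profile over the half-max
  # columns (the factor is computed from the measured FWHM, so it adapts to
  # each event). Falls back to a local raw-pixel average for partial events.
  fwhm <- crx[2L] - crx[1L]
  sigma_hat <- fwhm / (2 * sqrt(2 * log(2)))
  x_mid <- (crx[1L] + crx[2L]) / 2
  factor <- mean(exp(-(xx[cols_half] - x_mid)^2 / (2 * sigma_hat^2)))
  amplitude <- if (!partial && is.finite(factor) && factor > 0.3)
    peak_prof / factor else amp_fallback

  noise_level <- 2 * sigma_dff
  crt2 <- profile_crossings(tt, pt, pk_t_idx, noise_level)
  fd <- if (anyNA(crt2)) NA_real_ else crt2[2L] - crt2[1L]
  crx2 <- profile_crossings(xx, ps, pk_x_idx, noise_level)
  fw <- if (anyNA(crx2)) NA_real_ else crx2[2L] - crx2[1L]

  ttp <- if (is.na(crt2[1L])) NA_real_ else tt[pk_t_idx] - crt2[1L]

  tau_decay <- NA_real_
  dec <- seq.int(pk_t_idx, length(pt))
  z <- pt[dec]
  keep <- z > max(noise_level, 0.05 * peak_prof)
  stop_at <- which(!keep)[1L]
  if (!is.na(stop_at) && stop_at > 1L) keep[stop_at:length(keep)] <- FALSE
  if (sum(keep) >= 4L) {
    sl <- unname(stats::coef(stats::lm(log(z[keep]) ~ tt[dec][keep]))[2L])
    if (is.finite(sl) && sl < 0) tau_decay <- -1 / sl
  }

  data.frame(
    x_center = x_peak, t_center = t_peak, amplitude = amplitude,
    fwhm = fwhm, fdhm = fdhm, fw = fw, fd = fd, ttp = ttp,
    tau_decay = tau_decay,
    mass = spark_mass(max(amplitude, 0), fwhm),
    in_focus = amplitude > in_focus_min,
    is_ember = is.finite(fdhm) && fdhm > ember_fdhm,
    partial = partial
  )
}

#' Detect and parameterize all sparks in a line-scan image
#'
#' @param image a `LineScanImage`.
#' @param cri detection criterion.
#' @param ... passed to [detect_sparks()] and [spark_params()].
#' @return a `spark_table` data.frame (one row per spark) with attributes
#'   `scan_duration` (s) and `line_length` (um).
#' @export
analyze_sparks <- function(image, cri = 3.8, ...) {
  det <- detect_sparks(image, cri = cri)
  geo <- scan_geometry(image)
  if (det$n == 0L) {
    res <- data.frame(x_center = numeric(0), t_center = numeric(0),
                      amplitude = numeric(0), fwhm = numeric(0),
                      fdhm = numeric(0), fw = numeric(0), fd = numeric(0),
                      ttp = numeric(0), tau_decay = numeric(0),
                      mass = numeric(0), in_focus = logical(0),
                      is_ember = logical(0), partial = logical(0))
  } else {
    res <- do.call(rbind, lapply(det$regions, function(r)
      spark_params(det, r, ...)))
  }
  attr(res, "scan_duration") <- geo$scan_duration
  attr(res, "line_length") <- geo$line_length
  class(res) <- c("spark_table", "data.frame")
  res
}

#' Spark mass
#'
#' Volume-like index of a spark: `amplitude * 1.206 * FWHM^3`
#' (dF/F0 * um^3).
#'
#' @param amplitude spark amplitude (dF/F0), >= 0.
#' @param fwhm full width at half maximum (um), >= 0.
#' @return spark mass (vectorized).
#' @export
spark_mass <- function(amplitude, fwhm) {
  if (any(amplitude < 0, na.rm = TRUE) || any(fwhm < 0, na.rm = TRUE))
    stop("amplitude and fwhm must be non-negative")
  amplitude * 1.206 * fwhm^3
}

#' Spark frequency
#'
#' Number of in-focus, fully parameterized sparks per second per 100 um of
#' scanned line.
#'
#' @param sparks a `spark_table` (or data.frame with `in_focus`,
#'   `partial`).
#' @param scan_duration total scan duration (s); defaults to the table
#'   attribute. For multi-frame acquisitions this is the summed duration
#'   of all frames.
#' @param line_length scanned line length (um); defaults to the table
#'   attribute.
#' @return events s^-1 (100 um)^-1.
#' @export
spark_frequency <- function(sparks, scan_duration = NULL, line_length = NULL) {
  scan_duration <- scan_duration %||% attr(sparks, "scan_duration")
  line_length <- line_length %||% attr(sparks, "line_length")
  if (is.null(scan_duration) || scan_duration <= 0)
    stop("scan_duration must be positive")
  if (is.null(line_length) || line_length <= 0)
    stop("line_length must be positive")
  n <- if (nrow(sparks)) sum(sparks$in_focus & !sparks$partial) else 0L
  n / scan_duration / (line_length / 100)
}

#' Per-cell spark summary: frequency, mass, leak, embers
#'
#' Spark-mediated SR Ca2+ leak is the product of the mean in-focus spark
#' mass and the spark frequency. Embers are sparks with FDHM strictly
#' greater than `ember_fdhm` ms. Edge (`partial`) sparks are excluded from
#' all summary statistics.
#'
#' @param sparks a `spark_table`.
#' @param scan_duration,line_length scan geometry (see
#'   [spark_frequency()]).
#' @param ember_fdhm ember rule (ms, strict inequality).
#' @return a `SparkSummary`: `n_sparks`, `frequency`, `mean_mass`, `leak`,
#'   `ember_count`, `ember_fraction`, `has_embers`.
#' @export
summarize_sparks <- function(sparks, scan_duration = NULL, line_length = NULL,
                             ember_fdhm = 20) {
  sel <- if (nrow(sparks)) sparks$in_focus & !sparks$partial else logical(0)
  n <- sum(sel)
  freq <- spark_frequency(sparks, scan_duration, line_length)
  mean_mass <- if (n > 0) mean(sparks$mass[sel]) else NA_real_
  leak <- if (n > 0) mean_mass * freq else 0
  embers <- if (n > 0) sum(is.finite(sparks$fdhm[sel]) &
                           sparks$fdhm[sel] > ember_fdhm) else 0L
  structure(
    list(n_sparks = n, frequency = freq, mean_mass = mean_mass, leak = leak,
         ember_count = embers,
         ember_fraction = if (n > 0) embers / n else NA_real_,
         has_embers = embers > 0),
    class = "SparkSummary"
  )
}

#' @export
print.SparkSummary <- function(x, ...) {
  cat(sprintf("<SparkSummary> %d spark(s); freq %.3f /s/100um; mean mass %.2f; leak %.3f; embers %d\n",
              x$n_sparks, x$frequency, x$mean_mass, x$leak, x$ember_count))
  invisible(x)
}
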