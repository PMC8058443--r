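#' Specification of a synthetic spark-bearing line-scan image
#'
#' Sparks are separable kernels: Gaussian in space (SD `sigma_um`, so the
#' true FWHM is `2*sqrt(2*log(2))*sigma`), linear rise over `rise_ms` then
#' exponential decay with `tau_ms` in time (true FDHM
#' `rise/2 + tau*log(2)`). Defaults mirror a 0.5 kHz acquisition of a
#' 512 x 512 xt frame.
#'
#' @param n_lines,n_pixels image size (rows = time lines, cols = pixels).
#' @param pixel_size spatial pixel pitch (um).
#' @param line_period line period (ms).
#' @param baseline_f0 baseline fluorescence F0 (raw units).
#' @param background background fluorescence (raw units).
#' @param noise_sd Gaussian noise SD (raw units).
#' @param sparks `data.frame(x_um, t_ms, amplitude, sigma_um, rise_ms,
#'   tau_ms)` of ground-truth events (amplitude in dF/F0; centers are the
#'   peak position/time and are quantized to the sampling grid).
#' @param seed integer RNG seed.
#' @return a `LineScanSpec` list.
#' @export
linescan_spec <- function(n_lines = 512L, n_pixels = 512L, pixel_size = 0.15,
                          line_period = 2, baseline_f0 = 100, background = 10,
                          noise_sd = 10, sparks = NULL, seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (line_period <= 0) stop("line_period must be > 0")
  if (!is.null(sparks) && nrow(sparks)) {
    need <- c("x_um", "t_ms", "amplitude", "sigma_um", "rise_ms", "tau_ms")
    if (!all(need %in% names(sparks)))
      stop("sparks must have columns: ", paste(need, collapse = ", "))
    if (any(sparks$amplitude < 0)) stop("spark amplitudes must be >= 0")
    if (any(sparks$x_um < 0 | sparks$x_um > n_pixels * pixel_size |
            sparks$t_ms < 0 | sparks$t_ms > n_lines * line_period))
      stop("spark centered outside the image")
  }
  structure(
    list(n_lines = as.integer(n_lines), n_pixels = as.integer(n_pixels),
         pixel_size = pixel_size, line_period = line_period,
         baseline_f0 = baseline_f0, background = background,
         noise_sd = noise_sd, sparks = sparks, seed = seed),
    class = "LineScanSpec"
  )
}

#' Generate a synthetic line-scan image with ground-truth sparks
#'
#' @param spec a [linescan_spec()].
#' @return a `LineScanImage`; `ground_truth(image)$sparks` carries the
#'   event table augmented with the true FWHM and FDHM.
#' @export
gen_linescan <- function(spec) {
  stopifnot(inherits(spec, "LineScanSpec"))
  with_seed(spec$seed, {
    nl <- spec$n_lines; np <- spec$n_pixels
    xs <- (seq_len(np) - 1) * spec$pixel_size
    ts <- (seq_len(nl) - 1) * spec$line_period
    dff <- matrix(0, nl, np)
    sp <- spec$sparks
    if (!is.null(sp) && nrow(sp)) {
      # quantize centers to the sampling grid (peak attained at a sample)
      sp$x_um <- round(sp$x_um / spec$pixel_size) * spec$pixel_size
      sp$t_ms <- round(sp$t_ms / spec$line_period) * spec$line_period
      for (i in seq_len(nrow(sp))) {
        g <- exp(-(xs - sp$x_um[i])^2 / (2 * sp$sigma_um[i]^2))
        rel <- ts - (sp$t_ms[i] - sp$rise_ms[i])
        h <- numeric(nl)
        ris <- rel >= 0 & rel < sp$rise_ms[i]
        h[ris] <- rel[ris] / sp$rise_ms[i]
        dec <- rel >= sp$rise_ms[i]
        h[dec] <- exp(-(rel[dec] - sp$rise_ms[i]) / sp$tau_ms[i])
        dff <- dff + sp$amplitude[i] * outer(h, g)
      }
      sp$fwhm_um <- 2 * sqrt(2 * log(2)) * sp$sigma_um
      sp$fdhm_ms <- sp$rise_ms / 2 + sp$tau_ms * log(2)
    }
    m <- spec$background + spec$baseline_f0 * (1 + dff)
    if (spec$noise_sd > 0) m <- m + matrix(stats::rnorm(nl * np, 0, spec$noise_sd), nl, np)
    m <- pmax(m, 0)
    img <- linescan_image(m, pixel_size = spec$pixel_size,
                          line_period = spec$line_period,
                          background = spec$background)
    attr(img, "ground_truth") <- list(
      sparks = sp %||% data.frame(), f0 = spec$baseline_f0,
      noise_sd = spec$noise_sd
    )
    img
  })
}

#' Specification of a synthetic striated cell image
#'
#' Vertical bright bands (z-line/T-tubule staining) at `sarcomere_spacing`,
#' rendered as Gaussian intensity bands. Jitter and dropout act coherently
#' on whole bands (z-line displacement and loss, the microscopic picture of
#' T-tubule disarray). The default 2.0 um spacing places the spectral
#' fundamental at 0.5 um^-1.
#'
#' @param width,height image size (px).
#' @param pixel_size pixel pitch (um); default 78/1024.
#' @param sarcomere_spacing striation period (um).
#' @param jitter_sd SD of band positional jitter (um).
#' @param dropout_fraction per-segment probability that a band segment is
#'   missing (0-1).
#' @param noise_sd additive Gaussian intensity noise SD (8-bit units).
#' @param band_sigma Gaussian width of each band (um).
#' @param background_intensity,band_intensity 8-bit intensity levels.
#' @param cell_mask if `TRUE`, restrict the pattern to an inscribed
#'   horizontal ellipse (an elongated cell on dark background), which gives
#'   the image a well-defined principal axis for [orient_roi()].
#' @param seed integer RNG seed.
#' @return a `StriationImageSpec` list.
#' @export
striation_spec <- function(width = 1024L, height = 1024L,
                           pixel_size = 78 / 1024, sarcomere_spacing = 2,
                           jitter_sd = 0, dropout_fraction = 0, noise_sd = 0,
                           band_sigma = 0.25, background_intensity = 40,
                           band_intensity = 120, cell_mask = FALSE,
                           seed = 1L) {
  if (sarcomere_spacing <= 0) stop("sarcomere_spacing must be > 0")
  if (dropout_fraction < 0 || dropout_fraction > 1)
    stop("dropout_fraction must be in [0, 1]")
  if (sarcomere_spacing < 2 * pixel_size)
    stop("sarcomere_spacing smaller than 2 pixels cannot be rendered")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_size = pixel_size, sarcomere_spacing = sarcomere_spacing,
         jitter_sd = jitter_sd, dropout_fraction = dropout_fraction,
         noise_sd = noise_sd, band_sigma = band_sigma,
         background_intensity = background_intensity,
         band_intensity = band_intensity, cell_mask = cell_mask, seed = seed),
    class = "StriationImageSpec"
  )
}

#' Generate a synthetic striated cell image
#'
#' @param spec a [striation_spec()].
#' @return an 8-bit `CellImage`; `ground_truth(image)` holds the true
#'   spacing and spatial frequency.
#' @export
gen_striation_image <- function(spec) {
  stopifnot(inherits(spec, "StriationImageSpec"))
  with_seed(spec$seed, {
    w <- spec$width; h <- spec$height; px <- spec$pixel_size
    xs <- (seq_len(w) - 1) * px
    pos <- seq(spec$sarcomere_spacing / 2, w * px, by = spec$sarcomere_spacing)
    # jitter and dropout are coherent along each z-line: disarray displaces
    # or removes whole striations rather than widening them
    prof <- numeric(w)
    for (p in pos) {
      if (spec$dropout_fraction > 0 && stats::runif(1) < spec$dropout_fraction) next
      c0 <- p + if (spec$jitter_sd > 0) stats::rnorm(1, 0, spec$jitter_sd) else 0
      prof <- prof + exp(-(xs - c0)^2 / (2 * spec$band_sigma^2))
    }
    img <- matrix(rep(spec$background_intensity + spec$band_intensity * prof,
                      each = h), nrow = h)
    if (spec$cell_mask) {
      cy <- (h + 1) / 2; cx <- (w + 1) / 2
      a <- 0.46 * w; b <- 0.20 * h
      inside <- ((col(img) - cx) / a)^2 + ((row(img) - cy) / b)^2 <= 1
      img[!inside] <- 10
    }
    if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    img <- pmin(pmax(round(img), 0), 255)
    out <- cell_image(img, pixel_size = px)
    attr(out, "ground_truth") <- list(
      spacing_um = spec$sarcomere_spacing,
      frequency_um1 = 1 / spec$sarcomere_spacing
    )
    out
  })
}
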