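#' Confocal line-scan (xt) image
#'
#' Rows are successive time lines, columns are positions along the scanned
#' line.
#'
#' @param matrix numeric matrix of fluorescence values (rows = time).
#' @param pixel_size spatial pixel pitch (um).
#' @param line_period time per line (ms); 2 ms corresponds to 0.5 kHz.
#' @param background background fluorescence (same units as `matrix`).
#' @return an object of class `LineScanImage`.
#' @export
linescan_image <- function(matrix, pixel_size, line_period, background = 0) {
  if (!is.matrix(matrix)) stop("matrix must be a numeric matrix")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(line_period) || line_period <= 0) stop("line_period must be > 0")
  structure(
    list(matrix = matrix, pixel_size = pixel_size,
         line_period = line_period, background = background),
    class = "LineScanImage"
  )
}

#' 2D confocal cell image
#'
#' @param matrix numeric matrix of 8-bit gray intensities (0-255),
#'   rows = y, columns = x.
#' @param pixel_size pixel pitch (um); the default mirrors a 78 um field
#'   imaged at 1024 px.
#' @param roi optional region of interest, `list(rows = , cols = )` of index
#'   vectors.
#' @return an object of class `CellImage`.
#' @export
cell_image <- function(matrix, pixel_size = 78 / 1024, roi = NULL) {
  if (!is.matrix(matrix)) stop("matrix must be a numeric matrix")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.null(roi)) {
    if (!is.list(roi) || is.null(roi$rows) || is.null(roi$cols) ||
        !length(roi$rows) || !length(roi$cols)) {
      stop("roi must be list(rows =, cols =) with non-empty index vectors")
    }
  }
  structure(list(matrix = matrix, pixel_size = pixel_size, roi = roi),
            class = "CellImage")
}

#' @export
print.LineScanImage <- function(x, ...) {
  cat(sprintf("<LineScanImage> %d lines x %d px; %.3f um/px, %g ms/line (%.2f s, %.1f um)\n",
              nrow(x$matrix), ncol(x$matrix), x$pixel_size, x$line_period,
              nrow(x$matrix) * x$line_period / 1000,
              ncol(x$matrix) * x$pixel_size))
  invisible(x)
}

#' @export
print.CellImage <- function(x, ...) {
  cat(sprintf("<CellImage> %d x %d px; %.4f um/px (%.1f x %.1f um)\n",
              nrow(x$matrix), ncol(x$matrix), x$pixel_size,
              nrow(x$matrix) * x$pixel_size, ncol(x$matrix) * x$pixel_size))
  invisible(x)
}

# Line length (um) and total scan duration (s) of a line-scan image.
scan_geometry <- function(image) {
  list(line_length = ncol(image$matrix) * image$pixel_size,
       scan_duration = nrow(image$matrix) * image$line_period / 1000)
}
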