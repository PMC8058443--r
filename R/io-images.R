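#' Write an image as single-channel TIFF
#'
#' Cell images are written 8-bit (intensities 0-255), line-scan images
#' 16-bit (values clipped to 0-65535), matching the acquisition bit depths
#' the analyses assume.
#'
#' @param image a `CellImage` or `LineScanImage`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "CellImage")) {
    m <- pmin(pmax(round(image$matrix), 0), 255)
    tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  } else if (inherits(image, "LineScanImage")) {
    m <- pmin(pmax(round(image$matrix), 0), 65535)
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  } else {
    stop("not an image object")
  }
  invisible(path)
}

#' Read a single-channel TIFF as a typed image
#'
#' Pixel calibration is not stored in plain TIFFs, so `pixel_size` (and
#' `line_period` for line-scans) must be supplied. Multi-frame line-scan
#' stacks (e.g. 10 xt frames from one cell) are concatenated along time, so
#' the scan duration used by frequency computations is the sum over frames.
#'
#' @param path TIFF file path.
#' @param kind `"linescan"` or `"cell"`.
#' @param pixel_size pixel pitch (um); required.
#' @param line_period line period (ms); required for line-scans.
#' @param background background fluorescence (line-scans).
#' @return a `LineScanImage` or `CellImage`.
#' @export
read_image <- function(path, kind = c("linescan", "cell"),
                       pixel_size = NULL, line_period = NULL, background = 0) {
  kind <- match.arg(kind)
  if (is.null(pixel_size)) stop("pixel_size (um) is required to read an image")
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  for (f in frames) {
    if (length(dim(f)) == 3L)
      stop("multi-channel TIFF: extract a single channel before analysis")
  }
  if (kind == "linescan") {
    if (is.null(line_period)) stop("line_period (ms) is required for line-scan images")
    m <- do.call(rbind, frames)
    linescan_image(m, pixel_size = pixel_size, line_period = line_period,
                   background = background)
  } else {
    if (length(frames) > 1L)
      stop("expected a single-frame TIFF for a cell image; got ", length(frames), " frames")
    cell_image(frames[[1L]], pixel_size = pixel_size)
  }
}

#' Write a JSON run manifest
#'
#' Records package and R versions, the configuration in force, and MD5
#' hashes of the input files, so a pipeline run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param config named list of configuration values (seeds included).
#' @param inputs character vector of input file paths to hash.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config = list(), inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "cardioquant",
    version = as.character(utils::packageVersion("cardioquant")),
    r_version = R.version.string,
    config = config,
    input_md5 = hashes
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
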