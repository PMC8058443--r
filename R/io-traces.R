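#' Write a trace to delimited text
#'
#' The file carries a small `# key: value` header (kind, sampling rate and
#' unit, background, stimulus/caffeine annotations) followed by tab-separated
#' `time_ms` / `value` columns. Values are printed with 17 significant digits
#' so the file round-trips bit-identically through [read_trace()].
#'
#' @param trace a `VoltageTrace` or `FluorescenceTrace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  kind <- if (inherits(trace, "VoltageTrace")) "voltage" else
          if (inherits(trace, "FluorescenceTrace")) "fluorescence" else
          stop("not a trace object")
  unit <- if (kind == "voltage") "kHz" else "Hz"
  hdr <- c(
    "# cardioquant trace v1",
    paste0("# kind: ", kind),
    paste0("# sampling_rate: ", format(trace$sampling_rate, digits = 17)),
    paste0("# sampling_rate_unit: ", unit)
  )
  if (kind == "fluorescence") {
    hdr <- c(hdr, paste0("# background: ", format(trace$background, digits = 17)))
    if (!is.null(trace$caffeine_time))
      hdr <- c(hdr, paste0("# caffeine_time_ms: ", format(trace$caffeine_time, digits = 17)))
  }
  st <- if (kind == "voltage") trace$stimulus_times else trace$stim_times
  if (!is.null(st) && length(st))
    hdr <- c(hdr, paste0("# stim_times_ms: ", paste(format(st, digits = 17, trim = TRUE),
                                                    collapse = ",")))
  t <- trace_times(trace)
  body <- sprintf("%.17g\t%.17g", t, trace$samples)
  writeLines(c(hdr, "time_ms\tvalue", body), path)
  invisible(path)
}

#' Read a trace from delimited text
#'
#' Parses the header written by [write_trace()]. Sampling rates declared in
#' Hz or kHz are normalized to the canonical unit of each trace class
#' (kHz for voltage, Hz for fluorescence). Any non-numeric data row aborts
#' with the offending line number.
#'
#' @param path input file path.
#' @return a `VoltageTrace` or `FluorescenceTrace` according to the header.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  if (is.null(meta$sampling_rate))
    stop("trace file is missing sampling_rate metadata: ", path)
  rate <- as.numeric(meta$sampling_rate)
  unit <- tolower(meta$sampling_rate_unit %||% "hz")
  kind <- meta$kind %||% "fluorescence"
  body_idx <- which(!is_hdr)
  # skip the column-name row if present
  first <- lines[body_idx[1L]]
  if (grepl("[A-Za-z]", first)) body_idx <- body_idx[-1L]
  rows <- lines[body_idx]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, "[\t,;[:space:]]+")
  ncols <- lengths(parts)
  if (any(ncols < 2L)) {
    bad <- body_idx[which(ncols < 2L)[1L]]
    stop("malformed row (fewer than 2 columns) at line ", bad, " of ", path)
  }
  vals <- suppressWarnings(vapply(parts, function(p) as.numeric(p[2L]), 0))
  tms <- suppressWarnings(vapply(parts, function(p) as.numeric(p[1L]), 0))
  if (anyNA(vals) || anyNA(tms)) {
    bad <- body_idx[which(is.na(vals) | is.na(tms))[1L]]
    stop("non-numeric value at line ", bad, " of ", path)
  }
  if (kind == "voltage") {
    rate_khz <- if (unit == "hz") rate / 1000 else rate
    st <- if (!is.null(meta$stim_times_ms))
      as.numeric(strsplit(meta$stim_times_ms, ",")[[1L]]) else NULL
    voltage_trace(vals, rate_khz, stimulus_times = st)
  } else {
    rate_hz <- if (unit == "khz") rate * 1000 else rate
    st <- if (!is.null(meta$stim_times_ms))
      as.numeric(strsplit(meta$stim_times_ms, ",")[[1L]]) else NULL
    ct <- if (!is.null(meta$caffeine_time_ms)) as.numeric(meta$caffeine_time_ms) else NULL
    fluorescence_trace(vals, rate_hz,
                       background = as.numeric(meta$background %||% "0"),
                       stim_times = st, caffeine_time = ct)
  }
}
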