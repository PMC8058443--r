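#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that generators are reproducible without perturbing the session stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

# First downward crossing of `level` at or after index `from`, linearly
# interpolated between samples. Returns NA if the level is never crossed.
first_cross_down <- function(t, y, level, from = 1L) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- seq.int(from, n - 1L)
  hit <- which(y[idx] >= level & y[idx + 1L] < level)
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1L]]
  denom <- y[i] - y[i + 1L]
  frac <- if (denom == 0) 0 else (y[i] - level) / denom
  t[i] + frac * (t[i + 1L] - t[i])
}

# First upward crossing of `level` at or after index `from` (interpolated).
first_cross_up <- function(t, y, level, from = 1L) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- seq.int(from, n - 1L)
  hit <- which(y[idx] <= level & y[idx + 1L] > level)
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1L]]
  denom <- y[i + 1L] - y[i]
  frac <- if (denom == 0) 0 else (level - y[i]) / denom
  t[i] + frac * (t[i + 1L] - t[i])
}

# Runs of TRUE in a logical vector: runs shorter than `min_len` consecutive
# samples are dropped first, then surviving runs separated by gaps shorter
# than `merge_gap` samples are merged into single events. Returns a
# data.frame(start, end) of sample indices.
logical_runs <- function(mask, min_len = 1L, merge_gap = 0L) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  keep <- (ends - starts + 1L) >= min_len
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(data.frame(start = integer(0), end = integer(0)))
  if (merge_gap > 0L && length(starts) > 1L) {
    ms <- starts[1L]; me <- ends[1L]
    out_s <- integer(0); out_e <- integer(0)
    for (i in seq_along(starts)[-1L]) {
      if (starts[i] - me - 1L < merge_gap) {
        me <- ends[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
    starts <- c(out_s, ms); ends <- c(out_e, me)
  }
  data.frame(start = starts, end = ends)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# Centered moving average with edge replication (odd or even k).
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  p1 <- (k - 1L) %/% 2L
  p2 <- k - 1L - p1
  xp <- c(rep(x[1L], p1), x, rep(x[n], p2))
  cs <- cumsum(c(0, xp))
  (cs[(1:n) + k] - cs[1:n]) / k
}

# Running mean of length k down each column, edge-replicated.
run_mean_cols <- function(m, k) {
  k <- as.integer(k)
  if (k <= 1L) return(m)
  n <- nrow(m)
  p1 <- (k - 1L) %/% 2L
  p2 <- k - 1L - p1
  mp <- rbind(m[rep(1L, p1), , drop = FALSE], m, m[rep(n, p2), , drop = FALSE])
  cs <- rbind(0, apply(mp, 2L, cumsum))
  (cs[(1:n) + k, , drop = FALSE] - cs[1:n, , drop = FALSE]) / k
}

# Separable k x k boxcar smoothing with edge replication.
smooth_boxcar <- function(m, k = 3L) {
  t(run_mean_cols(t(run_mean_cols(m, k)), k))
}
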