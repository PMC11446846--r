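# Shared low-level helpers: smoothing, run extraction, integration.

#' Centered moving average
#'
#' Smooths a numeric series with a centered boxcar of `width` samples. The
#' window is truncated at the edges (partial means), so the output has the
#' same length as the input and no padding artifacts.
#'
#' @param x numeric vector.
#' @param width window width in samples; values < 2 return `x` unchanged.
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width < 2L) return(x)
  n <- length(x)
  half_lo <- (width - 1L) %/% 2L
  half_hi <- width %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Maximal runs of TRUE in a logical vector
#'
#' @param flag logical vector (NA treated as FALSE).
#' @return data.frame with 1-based columns `start`, `end` (inclusive) and
#'   `length`; zero rows when no run exists.
#' @keywords internal
true_runs <- function(flag) {
  flag <- !is.na(flag) & flag
  if (!any(flag)) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Trapezoidal integral of sampled series
#'
#' @param t sample times (strictly increasing).
#' @param y sampled values.
#' @return scalar integral.
#' @keywords internal
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Derive a reproducible substream seed
#'
#' Mixes a base seed with up to three counters into a value in 1..(2^31 - 2)
#' so independent random streams can be drawn per (trial, neuron) or per
#' fixture without one stream perturbing another.
#'
#' @param seed base integer seed.
#' @param a,b,c non-negative integer counters.
#' @return integer seed.
#' @keywords internal
substream_seed <- function(seed, a = 0L, b = 0L, c = 0L) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.double(seed %% m)
  for (k in c(a, b, c)) {
    s <- (s * 48271 + as.double(k) + 1) %% m
  }
  as.integer(s %% (m - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
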