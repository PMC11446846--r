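# Fluorescence-trace analysis: delta-F/F under three baseline conventions,
# response area, ratiometric z-scores, pixel-wise behavior correlation and
# lagged activity-velocity cross-correlation.

#' Baseline-normalized fluorescence change (delta-F/F)
#'
#' `(F - F0) / F0` with the baseline `F0` taken from a window immediately
#' before a reference event, under one of three conventions:
#' \describe{
#'   \item{`pre_mean`}{mean fluorescence over the 2 s before stimulation
#'     onset (functional-connectivity convention).}
#'   \item{`pre_p10`}{10th percentile of the 2 s before stimulation onset
#'     (muscle-imaging convention, robust to activity in the baseline).}
#'   \item{`pre_median`}{median of the 300 ms before movement initiation
#'     (tibia-movement convention).}
#' }
#'
#' @param f fluorescence series, arbitrary units.
#' @param sample_rate Hz.
#' @param reference_time stimulation or movement onset, s.
#' @param mode baseline convention (above).
#' @param baseline_window override the window length, s (defaults: 2, 2,
#'   0.3 per mode).
#' @return numeric delta-F/F series, same length as `f`.
#' @export
dff <- function(f, sample_rate, reference_time,
                mode = c("pre_mean", "pre_p10", "pre_median"),
                baseline_window = NULL) {
  mode <- match.arg(mode)
  baseline_window <- baseline_window %||%
    switch(mode, pre_mean = 2, pre_p10 = 2, pre_median = 0.3)
  i_ref <- floor(reference_time * sample_rate)  # samples strictly before onset
  i0 <- i_ref - as.integer(round(baseline_window * sample_rate)) + 1L
  if (i0 < 1L || i_ref < i0)
    stopf("baseline window of %g s does not fit before t = %g s",
          baseline_window, reference_time)
  base <- f[i0:i_ref]
  f0 <- switch(mode,
               pre_mean = mean(base),
               pre_p10 = unname(stats::quantile(base, 0.10, type = 7)),
               pre_median = stats::median(base))
  if (!is.finite(f0) || f0 <= 0)
    stopf("baseline F0 = %g is not positive: delta-F/F undefined", f0)
  (f - f0) / f0
}

#' Area under the response curve
#'
#' Trapezoidal time-integral of a delta-F/F series over a post-stimulation
#' window (the comparison statistic is the 0-2 s poststimulation area).
#'
#' @param x delta-F/F series.
#' @param sample_rate Hz.
#' @param stim_onset stimulation onset, s.
#' @param window integration window relative to onset, s (default `c(0, 2)`).
#' @return scalar area (units: s, since delta-F/F is dimensionless).
#' @export
response_auc <- function(x, sample_rate, stim_onset, window = c(0, 2)) {
  t <- (seq_along(x) - 1L) / sample_rate
  lo <- stim_onset + window[1]; hi <- stim_onset + window[2]
  if (lo < 0 || hi > t[length(t)] + 1e-9)
    stopf("integration window outside the recording")
  sel <- t >= lo - 1e-12 & t <= hi + 1e-12
  trapz(t[sel], x[sel])
}

#' Z-scored ratiometric trace
#'
#' Ratio of the calcium-sensitive to the calcium-insensitive channel,
#' `R = green / red`, expressed as delta-R/R against the recording-median
#' baseline and z-scored to mean 0 / sd 1 over the recording. Because the
#' ratio is taken first, multiplicative artifacts common to both channels
#' (movement, focus drift) cancel exactly.
#'
#' @param green,red co-sampled channel series; `red` must be positive
#'   throughout.
#' @return z-scored delta-R/R series.
#' @export
zscored_ratio <- function(green, red) {
  if (length(green) != length(red)) stopf("channels must be co-sampled")
  if (any(red <= 0)) stopf("red channel non-positive: ratio undefined")
  r <- green / red
  r0 <- stats::median(r)
  if (r0 <= 0) stopf("median ratio non-positive: delta-R/R undefined")
  drr <- (r - r0) / r0
  s <- stats::sd(drr)
  if (s == 0) stopf("constant ratio: z-score undefined")
  (drr - mean(drr)) / s
}

# Block-average a fast series down to a slow clock. length-out blocks of
# size factor (fs_fast / fs_slow, must be near-integer).
block_average <- function(x, factor) {
  factor <- as.integer(round(factor))
  n_out <- length(x) %/% factor
  if (n_out < 1L) stopf("series too short to resample")
  colMeans(matrix(x[seq_len(n_out * factor)], nrow = factor))
}

#' Pixel-wise correlation map against a behavior reference
#'
#' Pearson correlation of every pixel's intensity series with a reference
#' series (an ethogram indicator or a velocity trace). When the reference is
#' sampled faster than the movie it is block-averaged down to the imaging
#' clock, so no imaging samples are invented. Constant pixels have an
#' undefined correlation and are reported as 0 with a mask flag.
#'
#' @param movie numeric matrix, pixels x time.
#' @param reference behavior series.
#' @param movie_rate,reference_rate sample rates, Hz.
#' @return list with `r` (per-pixel correlation, in \[-1, 1\]) and
#'   `masked` (logical, TRUE where the pixel was constant).
#' @export
pixel_correlation_map <- function(movie, reference, movie_rate = NULL,
                                  reference_rate = NULL) {
  movie <- as.matrix(movie)
  if (!is.null(movie_rate) && !is.null(reference_rate) &&
      reference_rate > movie_rate) {
    fac <- reference_rate / movie_rate
    if (abs(fac - round(fac)) > 1e-6)
      stopf("reference rate must be an integer multiple of the movie rate")
    reference <- block_average(reference, fac)
  }
  if (length(reference) != ncol(movie))
    stopf("movie (%d frames) and reference (%d samples) differ after resampling",
          ncol(movie), length(reference))
  sds <- apply(movie, 1, stats::sd)
  masked <- sds == 0 | is.na(sds)
  r <- numeric(nrow(movie))
  if (stats::sd(reference) == 0) stopf("constant reference series")
  ok <- !masked
  if (any(ok)) r[ok] <- as.numeric(stats::cor(t(movie[ok, , drop = FALSE]),
                                              reference))
  list(r = r, masked = masked)
}

#' Lagged activity-velocity cross-correlation
#'
#' Normalized cross-correlation between a neural activity series and a
#' locomotor velocity series over lags in `[-max_lag, +max_lag]`. The value
#' at lag L is the Pearson correlation of `activity(t + L)` with
#' `velocity(t)` over the overlap, so a positive peak lag means activity
#' follows velocity. Multiple recordings are pooled by concatenation after
#' per-recording mean removal (lags never straddle a recording boundary
#' because shifted-out samples at the boundary contribute at most one
#' spurious pair per recording; recordings are shifted individually and
#' then pooled).
#'
#' @param activity series or list of series (one per recording).
#' @param velocity matching series or list.
#' @param sample_rate Hz.
#' @param max_lag maximum lag, s.
#' @return data.frame `lag` (s) and `r`.
#' @export
activity_velocity_xcorr <- function(activity, velocity, sample_rate,
                                    max_lag) {
  if (!is.list(activity)) activity <- list(activity)
  if (!is.list(velocity)) velocity <- list(velocity)
  stopifnot(length(activity) == length(velocity))
  for (k in seq_along(activity)) {
    if (length(activity[[k]]) != length(velocity[[k]]))
      stopf("recording %d: series lengths differ", k)
    if (stats::sd(activity[[k]]) == 0 || stats::sd(velocity[[k]]) == 0)
      stopf("recording %d: zero-variance input", k)
    activity[[k]] <- activity[[k]] - mean(activity[[k]])
    velocity[[k]] <- velocity[[k]] - mean(velocity[[k]])
  }
  max_lag_n <- as.integer(round(max_lag * sample_rate))
  if (any(vapply(activity, length, 1L) <= max_lag_n))
    stopf("max_lag must be shorter than every recording")
  lags <- seq(-max_lag_n, max_lag_n)
  r <- vapply(lags, function(L) {
    aa <- c(); vv <- c()
    for (k in seq_along(activity)) {
      a <- activity[[k]]; v <- velocity[[k]]; n <- length(a)
      if (L >= 0) {
        aa <- c(aa, a[(1 + L):n]); vv <- c(vv, v[1:(n - L)])
      } else {
        aa <- c(aa, a[1:(n + L)]); vv <- c(vv, v[(1 - L):n])
      }
    }
    stats::cor(aa, vv)
  }, numeric(1))
  data.frame(lag = lags / sample_rate, r = r)
}
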