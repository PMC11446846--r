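# Swing-initiation zone (SIZ): the femur-tibia angle range from which legs
# launch swings. Forward walking initiates swings from flexed angles, so the
# zone is everything below the 25th percentile of swing-onset angles;
# backward walking initiates from extended angles, above the 75th percentile.

#' Define the swing-initiation zone
#'
#' The SIZ threshold is a percentile of the femur-tibia flexion angles
#' observed at swing onset: the 25th percentile for forward walking (zone =
#' angles below it) or the 75th percentile for backward walking (zone =
#' angles above it). Percentiles use linear interpolation between closest
#' ranks (`stats::quantile` type 7), fixed here so thresholds are
#' reproducible.
#'
#' @param onset_angles femur-tibia angles at swing onset, degrees.
#' @param direction `"forward"` or `"backward"`.
#' @param min_n minimum number of onset angles required (default 20).
#' @return a `siz_definition`: list with `direction`, `threshold` (degrees)
#'   and `side` (`"below"` for forward, `"above"` for backward).
#' @export
define_siz <- function(onset_angles, direction = c("forward", "backward"),
                       min_n = 20L) {
  direction <- match.arg(direction)
  onset_angles <- onset_angles[!is.na(onset_angles)]
  if (length(onset_angles) < min_n)
    stopf("need at least %d swing-onset angles to define the zone (got %d)",
          min_n, length(onset_angles))
  if (direction == "forward") {
    thr <- unname(stats::quantile(onset_angles, 0.25, type = 7))
    side <- "below"
  } else {
    thr <- unname(stats::quantile(onset_angles, 0.75, type = 7))
    side <- "above"
  }
  structure(list(direction = direction, threshold = thr, side = side),
            class = "siz_definition")
}

#' @export
print.siz_definition <- function(x, ...) {
  cat(sprintf("siz_definition: %s walking, zone %s %.2f deg\n",
              x$direction, x$side, x$threshold))
  invisible(x)
}

# per-frame zone membership
in_siz <- function(angle, siz) {
  if (siz$side == "below") angle < siz$threshold else angle > siz$threshold
}

#' Per-trial swing-initiation-zone metrics
#'
#' For each trial window: the SIZ count (number of times the femur-tibia
#' angle enters the zone), the dwell times (time spent in the zone per
#' entry) and the percentage of SIZ events during which the leg launches a
#' swing (a swing onset falls inside the event). An entry is a strict
#' crossing — previous frame outside, current frame inside — except that a
#' trial starting inside the zone counts as one entry at its first frame.
#' Trials with zero events have an undefined percentage (`NA`, flagged via
#' the count) and are excluded from averages by the caller.
#'
#' @param angle per-frame femur-tibia angle, degrees (one leg).
#' @param gait the matching `gait_trace` (same leg, same clock).
#' @param siz a [define_siz()] result.
#' @param trials data.frame with `t_start`, `t_end` (s, half-open windows).
#' @param frame_rate Hz; defaults to the gait trace's rate.
#' @return list with `per_trial` (data.frame `trial`, `siz_count`,
#'   `n_with_swing`, `pct_swings_in_siz`) and `dwell_times` (list of numeric
#'   vectors, s, per trial).
#' @export
siz_metrics <- function(angle, gait, siz, trials,
                        frame_rate = gait$frame_rate) {
  stopifnot(inherits(gait, "gait_trace"), inherits(siz, "siz_definition"))
  n <- length(angle)
  if (n != length(gait$phase))
    stopf("angle trace and gait trace have different lengths")
  inz <- in_siz(angle, siz)
  swing_onsets <- gait$segments$onset[gait$segments$label == "swing"]

  n_tr <- nrow(trials)
  counts <- integer(n_tr); with_swing <- integer(n_tr)
  dwell <- vector("list", n_tr)
  for (k in seq_len(n_tr)) {
    f0 <- floor(trials$t_start[k] * frame_rate) + 1L
    f1 <- min(ceiling(trials$t_end[k] * frame_rate), n)  # last frame, inclusive
    if (f1 < f0) next
    dw <- numeric(0); cnt <- 0L; ws <- 0L
    f <- f0
    while (f <= f1) {
      entered <- inz[f] && (f == f0 || !inz[f - 1L])
      if (entered) {
        ex <- f
        while (ex <= f1 && inz[ex]) ex <- ex + 1L  # first frame out (or past window)
        cnt <- cnt + 1L
        dw <- c(dw, (ex - f) / frame_rate)
        if (any(swing_onsets >= f & swing_onsets < ex)) ws <- ws + 1L
        f <- ex
      } else {
        f <- f + 1L
      }
    }
    counts[k] <- cnt; with_swing[k] <- ws; dwell[[k]] <- dw
  }
  per_trial <- data.frame(trial = seq_len(n_tr), siz_count = counts,
                          n_with_swing = with_swing,
                          pct_swings_in_siz =
                            ifelse(counts > 0, 100 * with_swing / counts,
                                   NA_real_))
  list(per_trial = per_trial, dwell_times = dwell)
}
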