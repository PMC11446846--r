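# Free-walking arena analysis: velocities and rotation from planar tracker
# output, pivot and stop detection, per-trial distance/rotation, sucrose
# preference and food-zone interaction metrics.
#
# Units: mm, degrees, seconds; frames 1-based; windows half-open.

#' Per-frame kinematics from a planar tracker table
#'
#' Finite-difference translational and angular velocity from x/y/heading.
#' Heading is unwrapped before differencing; the angular velocity is
#' reported as an absolute value and rotation is the running time-integral
#' of that absolute angular velocity. Optional smoothing is a centered
#' moving average.
#'
#' @param track data.frame with `x`, `y` (mm) and `heading` (degrees on
#'   \[0, 360)); an optional `t` column (s) is checked for uniform sampling.
#' @param frame_rate Hz (arena videos run at 30).
#' @param smooth_window smoothing window, s; `NULL` or 0 for none.
#' @return data.frame `frame`, `t`, `v_trans` (mm/s), `v_ang` (deg/s,
#'   absolute), `rotation` (deg, cumulative).
#' @export
track_kinematics <- function(track, frame_rate = 30, smooth_window = NULL) {
  req <- c("x", "y", "heading")
  if (!all(req %in% names(track)))
    stopf("track needs columns: %s", paste(req, collapse = ", "))
  n <- nrow(track)
  if (n < 2L) stopf("need at least 2 frames")
  if ("t" %in% names(track)) {
    dts <- diff(track$t)
    if (max(abs(dts - 1 / frame_rate)) > 1e-6 / frame_rate)
      stopf("timestamps are not uniform at %g Hz", frame_rate)
  }
  dx <- diff(track$x); dy <- diff(track$y)
  v_trans <- c(NA, sqrt(dx^2 + dy^2) * frame_rate)
  v_trans[1] <- v_trans[2]
  # unwrap heading: remove 360-degree jumps before differencing
  dh <- diff(track$heading)
  dh <- dh - 360 * round(dh / 360)
  v_ang_signed <- c(NA, dh * frame_rate)
  v_ang_signed[1] <- v_ang_signed[2]
  v_ang <- abs(v_ang_signed)
  if (!is.null(smooth_window) && smooth_window > 0) {
    w <- max(1L, as.integer(round(smooth_window * frame_rate)))
    v_trans <- moving_average(v_trans, w)
    v_ang <- moving_average(v_ang, w)
  }
  data.frame(frame = seq_len(n), t = (seq_len(n) - 1L) / frame_rate,
             v_trans = v_trans, v_ang = v_ang,
             rotation = c(0, cumsum(abs(dh))))
}

#' Detect pivots (turning in place)
#'
#' Pivots are periods of high angular and low translational velocity: after
#' smoothing with a 0.5 s window, absolute angular velocity above two
#' rotations per second (720 deg/s) while translational velocity stays below
#' 5 mm/s.
#'
#' @param v_trans,v_ang per-frame velocities (mm/s, deg/s) on the same
#'   clock.
#' @param frame_rate Hz.
#' @param smooth_window smoothing window, s (default 0.5).
#' @param ang_thresh angular threshold, deg/s (default 720).
#' @param trans_thresh translational threshold, mm/s (default 5).
#' @return data.frame `t_start`, `t_end` (s, half-open), `duration_ms`,
#'   `label = "pivot"`.
#' @export
detect_pivots <- function(v_trans, v_ang, frame_rate = 30,
                          smooth_window = 0.5, ang_thresh = 720,
                          trans_thresh = 5) {
  if (length(v_trans) != length(v_ang))
    stopf("velocity series must share one clock")
  w <- max(1L, as.integer(round(smooth_window * frame_rate)))
  vt <- moving_average(v_trans, w)
  va <- moving_average(v_ang, w)
  runs <- true_runs(va > ang_thresh & vt < trans_thresh)
  data.frame(t_start = (runs$start - 1L) / frame_rate,
             t_end = runs$end / frame_rate,
             duration_ms = runs$length * 1000 / frame_rate,
             label = rep("pivot", nrow(runs)))
}

#' Detect stopping bouts in arena walking
#'
#' Two published variants. `food_assay`: smoothed translational velocity
#' below 2 mm/s for at least ten frames (robust to tracker jitter while the
#' fly feeds). `freewalk`: smoothed velocity below a 1.5 mm/s threshold; the
#' original description leaves the smoothing/threshold split ambiguous, so
#' both are exposed (defaults: 1.5 mm/s threshold, 0.5 s smoothing, no
#' minimum duration).
#'
#' @param v_trans translational velocity, mm/s.
#' @param frame_rate Hz.
#' @param variant `"food_assay"` or `"freewalk"`.
#' @param threshold mm/s; default per variant.
#' @param smooth_window s (default 0.5).
#' @param min_frames minimum run length in frames; default 10 for
#'   `food_assay`, 1 for `freewalk`.
#' @return data.frame `t_start`, `t_end` (s), `duration_ms`,
#'   `label = "stop"`.
#' @export
detect_stops <- function(v_trans, frame_rate = 30,
                         variant = c("food_assay", "freewalk"),
                         threshold = NULL, smooth_window = 0.5,
                         min_frames = NULL) {
  variant <- match.arg(variant)
  threshold <- threshold %||% if (variant == "food_assay") 2 else 1.5
  min_frames <- min_frames %||% if (variant == "food_assay") 10L else 1L
  w <- max(1L, as.integer(round(smooth_window * frame_rate)))
  v <- moving_average(v_trans, w)
  runs <- true_runs(v < threshold)
  runs <- runs[runs$length >= min_frames, , drop = FALSE]
  data.frame(t_start = (runs$start - 1L) / frame_rate,
             t_end = runs$end / frame_rate,
             duration_ms = runs$length * 1000 / frame_rate,
             label = rep("stop", nrow(runs)))
}

#' Distance and rotation per stimulation trial
#'
#' Path length and accumulated rotation (integral of absolute angular
#' velocity) over `[onset, onset + horizon)` for each stimulation onset.
#' The standard analysis horizon is the first 2 s of stimulation. Horizons
#' extending beyond the recording are truncated and flagged.
#'
#' @param track data.frame with `x`, `y`, `heading`.
#' @param onsets stimulation onsets, s.
#' @param horizon window length, s (default 2).
#' @param frame_rate Hz.
#' @return data.frame `onset`, `distance` (mm), `rotation` (deg),
#'   `truncated` (logical).
#' @export
trial_metrics <- function(track, onsets, horizon = 2, frame_rate = 30) {
  n <- nrow(track)
  dur <- n / frame_rate
  if (any(onsets < 0 | onsets >= dur)) stopf("onset(s) outside the recording")
  dh <- diff(track$heading)
  dh <- abs(dh - 360 * round(dh / 360))
  step_len <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  out <- data.frame(onset = onsets, distance = NA_real_,
                    rotation = NA_real_, truncated = FALSE)
  for (k in seq_along(onsets)) {
    f0 <- floor(onsets[k] * frame_rate) + 1L
    f1 <- floor((onsets[k] + horizon) * frame_rate) + 1L  # frame at window end
    if (f1 > n) { f1 <- n; out$truncated[k] <- TRUE }
    idx <- seq(f0, max(f0, f1 - 1L))  # steps f -> f+1
    if (f1 > f0) {
      out$distance[k] <- sum(step_len[idx])
      out$rotation[k] <- sum(dh[idx])
    } else {
      out$distance[k] <- 0; out$rotation[k] <- 0
    }
  }
  out
}

#' Two-choice preference index
#'
#' Time-based preference for the sucrose half of the arena over the blank
#' half: `pi = (t_sucrose - t_blank) / (t_sucrose + t_blank)`, in
#' \[-1, 1\]. Frames without a side label are ignored.
#'
#' @param side per-frame side label: `"sucrose"`, `"blank"` or `NA`.
#' @param frame_rate Hz.
#' @return list with `pi`, `t_sucrose` and `t_blank` (s).
#' @export
preference_index <- function(side, frame_rate = 30) {
  ts <- sum(side == "sucrose", na.rm = TRUE) / frame_rate
  tb <- sum(side == "blank", na.rm = TRUE) / frame_rate
  if (ts + tb == 0) stopf("no labeled frames: preference undefined")
  list(pi = (ts - tb) / (ts + tb), t_sucrose = ts, t_blank = tb)
}

#' Food-zone interaction configuration
#'
#' @param blob_center `(x, y)` of the sucrose blob, mm.
#' @param interaction_radius distance to the blob center counting as
#'   interacting, mm (default 3 — fly and blob are both about 3 mm).
#' @param zone_diameter diameter of the food zone circle, mm (default 6).
#' @param post_encounter_window analysis window after first encounter, s
#'   (default 5).
#' @return a `food_zone_config` list.
#' @export
food_zone_config <- function(blob_center, interaction_radius = 3,
                             zone_diameter = 6, post_encounter_window = 5) {
  if (zone_diameter < 0 || interaction_radius < 0)
    stopf("zone geometry must be non-negative")
  structure(list(blob_center = as.numeric(blob_center),
                 interaction_radius = interaction_radius,
                 zone_diameter = zone_diameter,
                 post_encounter_window = post_encounter_window),
            class = "food_zone_config")
}

#' Stopping and velocities inside the food zone
#'
#' Quantifies behavior in the 5 s after the fly first finds the sucrose:
#' stop bouts (food-assay definition) and mean translational/angular
#' velocity, restricted to frames inside the food zone during
#' `[encounter, encounter + window)`. The supplied encounter frame is
#' validated as the first frame within the interaction radius.
#'
#' @param track data.frame with `x`, `y`, `heading`.
#' @param cfg a [food_zone_config()].
#' @param encounter_frame 1-based index of the first interaction frame; if
#'   `NULL` it is derived from the geometry.
#' @param frame_rate Hz.
#' @return list with `encounter_frame`, `stop_bouts` (data.frame, times
#'   relative to recording start), `v_trans_in_zone`, `v_ang_in_zone`
#'   (means) and `entered` (FALSE with empty metrics when the fly never
#'   interacts).
#' @export
food_zone_metrics <- function(track, cfg, encounter_frame = NULL,
                              frame_rate = 30) {
  stopifnot(inherits(cfg, "food_zone_config"))
  d <- sqrt((track$x - cfg$blob_center[1])^2 +
              (track$y - cfg$blob_center[2])^2)
  first <- which(d <= cfg$interaction_radius)[1]
  if (is.na(first)) {
    if (!is.null(encounter_frame))
      stopf("encounter_frame given but the fly never comes within %g mm",
            cfg$interaction_radius)
    return(list(entered = FALSE, encounter_frame = NA_integer_,
                stop_bouts = detect_stops(numeric(0), frame_rate)[0, ],
                v_trans_in_zone = NA_real_, v_ang_in_zone = NA_real_))
  }
  if (is.null(encounter_frame)) encounter_frame <- first
  if (encounter_frame != first)
    stopf("encounter_frame %d inconsistent with geometry (first interaction at frame %d)",
          encounter_frame, first)
  kin <- track_kinematics(track, frame_rate)
  f1 <- min(encounter_frame +
              as.integer(round(cfg$post_encounter_window * frame_rate)) - 1L,
            nrow(track))
  win <- encounter_frame:f1
  in_zone <- d[win] <= cfg$zone_diameter / 2
  stops <- detect_stops(kin$v_trans[win], frame_rate, variant = "food_assay")
  stops$t_start <- stops$t_start + (encounter_frame - 1L) / frame_rate
  stops$t_end <- stops$t_end + (encounter_frame - 1L) / frame_rate
  list(entered = TRUE, encounter_frame = encounter_frame,
       stop_bouts = stops,
       v_trans_in_zone = mean(kin$v_trans[win][in_zone]),
       v_ang_in_zone = mean(kin$v_ang[win][in_zone]))
}
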