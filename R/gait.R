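# 3D leg kinematics on the spherical treadmill: sphere fitting, swing/stance
# classification with short-phase filtering, joint angles, stop bouts,
# swing-duration and grooming-stability summaries.
#
# Conventions: coordinates are world-frame mm; frames are 1-based; segment
# intervals are half-open [onset, offset) in frames.

#' Fit a sphere to tarsal-tip coordinates
#'
#' The treadmill ball is not tracked directly; its position and radius are
#' recovered by iterative least squares on the tracked tarsal tips, which
#' contact the surface during stance. Minimizes the squared orthogonal
#' distance `sum((|p - c| - r)^2)` by Gauss-Newton, started from the
#' algebraic (linear) sphere fit unless an initial fit is supplied.
#'
#' @param points numeric matrix (n x 3) of tip coordinates, mm; needs at
#'   least 4 non-coplanar points.
#' @param init optional starting `ball_fit` (or list with `center`,
#'   `radius`).
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol convergence tolerance on the parameter update, mm.
#' @return a `ball_fit`: list with `center` (length 3), `radius`,
#'   `rms_residual` (mm) and `iterations`.
#' @export
fit_ball <- function(points, init = NULL, max_iter = 100L, tol = 1e-10) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stopf("points must be an n x 3 matrix")
  points <- points[stats::complete.cases(points), , drop = FALSE]
  n <- nrow(points)
  if (n < 4L) stopf("sphere fit needs at least 4 points")
  ctr <- scale(points, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stopf("points are coplanar or degenerate: sphere unidentifiable")

  if (is.null(init)) {
    # algebraic initialization: |p|^2 = 2 p.c + (r^2 - |c|^2) is linear
    A <- cbind(2 * points, 1)
    b <- rowSums(points^2)
    beta <- qr.solve(A, b)
    c0 <- beta[1:3]
    r0 <- sqrt(max(beta[4] + sum(c0^2), .Machine$double.eps))
  } else {
    c0 <- as.numeric(init$center)
    r0 <- init$radius
  }

  theta <- c(c0, r0)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    d <- sqrt(rowSums((points - matrix(theta[1:3], n, 3, byrow = TRUE))^2))
    d <- pmax(d, .Machine$double.eps)
    resid <- d - theta[4]
    J <- cbind(-(points - matrix(theta[1:3], n, 3, byrow = TRUE)) / d, -1)
    step <- tryCatch(qr.solve(J, -resid), error = function(e) NULL)
    if (is.null(step)) break
    theta <- theta + step
    if (sqrt(sum(step^2)) < tol) break
  }
  d <- sqrt(rowSums((points - matrix(theta[1:3], n, 3, byrow = TRUE))^2))
  structure(list(center = unname(theta[1:3]), radius = unname(theta[4]),
                 rms_residual = sqrt(mean((d - theta[4])^2)),
                 iterations = iters),
            class = "ball_fit")
}

#' @export
print.ball_fit <- function(x, ...) {
  cat(sprintf("ball_fit: center (%.4f, %.4f, %.4f) mm, radius %.4f mm, rms %.2g mm (%d it.)\n",
              x$center[1], x$center[2], x$center[3], x$radius,
              x$rms_residual, x$iterations))
  invisible(x)
}

# Segment a logical stance vector into half-open [onset, offset) runs.
phase_segments <- function(stance, frame_rate) {
  r <- rle(stance)
  ends <- cumsum(r$lengths)
  onsets <- ends - r$lengths + 1L
  data.frame(onset = onsets, offset = ends + 1L,
             label = ifelse(r$values, "stance", "swing"),
             duration_ms = r$lengths * 1000 / frame_rate)
}

#' Classify swing and stance from tarsal-tip distance to the ball
#'
#' A tip within a fractional band of the fitted radius about the ball
#' surface is in stance; otherwise in swing. The conventional band is 0.05%
#' of the radius (`stance_tol_frac = 5e-4`); pass `0.05` to read the band as
#' a 5% fraction instead. Phases shorter than `min_phase_ms` are filtered
#' out by merging them into the longer flanking phase (ties go to the
#' preceding phase), so no output segment is shorter than the minimum.
#'
#' @param tips n x 3 matrix of one leg's tarsal-tip coordinates, mm.
#' @param ball a [fit_ball()] result.
#' @param frame_rate Hz (the kinematics rig records at 200).
#' @param stance_tol_frac half-width of the stance band as a fraction of the
#'   radius.
#' @param min_phase_ms minimum surviving phase duration, ms.
#' @return a `gait_trace`: list with `phase` (character per frame, "stance"
#'   or "swing"), `segments` (data.frame `onset`, `offset` half-open frames,
#'   `label`, `duration_ms`) and `frame_rate`.
#' @export
classify_gait <- function(tips, ball, frame_rate = 200,
                          stance_tol_frac = 5e-4, min_phase_ms = 10) {
  stopifnot(inherits(ball, "ball_fit"))
  if (is.null(frame_rate) || is.na(frame_rate) || frame_rate <= 0)
    stopf("frame_rate must be a positive number of Hz")
  tips <- as.matrix(tips)
  d <- sqrt(rowSums((tips - matrix(ball$center, nrow(tips), 3,
                                   byrow = TRUE))^2))
  stance <- abs(d - ball$radius) <= stance_tol_frac * ball$radius

  seg <- phase_segments(stance, frame_rate)
  # iteratively absorb the shortest sub-threshold segment into the longer
  # flanking phase (tie -> preceding); re-merge and repeat
  repeat {
    short <- which(seg$duration_ms < min_phase_ms)
    if (!length(short) || nrow(seg) == 1L) break
    k <- short[which.min(seg$duration_ms[short])]
    if (k == 1L) {
      new_label <- seg$label[2L]
    } else if (k == nrow(seg)) {
      new_label <- seg$label[k - 1L]
    } else {
      prev_d <- seg$duration_ms[k - 1L]
      next_d <- seg$duration_ms[k + 1L]
      new_label <- if (next_d > prev_d) seg$label[k + 1L] else seg$label[k - 1L]
    }
    stance[seg$onset[k]:(seg$offset[k] - 1L)] <- new_label == "stance"
    seg <- phase_segments(stance, frame_rate)
  }
  structure(list(phase = ifelse(stance, "stance", "swing"), segments = seg,
                 frame_rate = frame_rate),
            class = "gait_trace")
}

#' @export
print.gait_trace <- function(x, ...) {
  cat(sprintf("gait_trace: %d frames @ %g Hz, %d segments (%d swing)\n",
              length(x$phase), x$frame_rate, nrow(x$segments),
              sum(x$segments$label == "swing")))
  invisible(x)
}

#' Flexion angle at a joint
#'
#' Interior angle at `p_joint` between the proximal and distal limb
#' segments, in degrees (180 = fully extended, collinear). Inputs may be
#' single points (length 3) or n x 3 matrices of per-frame positions.
#'
#' @param p_prox,p_joint,p_dist points in mm.
#' @return angle(s) in degrees, in \[0, 180\].
#' @export
flexion_angle <- function(p_prox, p_joint, p_dist) {
  as_mat <- function(p) if (is.null(dim(p))) matrix(p, 1L) else as.matrix(p)
  u <- as_mat(p_prox) - as_mat(p_joint)
  w <- as_mat(p_dist) - as_mat(p_joint)
  nu <- sqrt(rowSums(u^2)); nw <- sqrt(rowSums(w^2))
  if (any(nu <= 0 | nw <= 0)) stopf("zero-length limb segment")
  cosang <- pmin(1, pmax(-1, rowSums(u * w) / (nu * nw)))
  ang <- acos(cosang) * 180 / pi
  if (length(ang) == 1L) ang[[1L]] else ang
}

#' Detect stopping bouts from ball velocity
#'
#' A stopping bout is a period during which the average ball velocity stays
#' below `v_thresh` for at least `min_dur_ms`. "Average" is implemented as a
#' centered running mean of `smooth_ms` (default equal to the minimum
#' duration); maximal sub-threshold runs shorter than the minimum are
#' discarded, so every returned bout satisfies the duration floor.
#'
#' @param velocity ball speed, mm/s, uniformly sampled.
#' @param frame_rate Hz (the ball tracker runs at 50).
#' @param v_thresh threshold, mm/s (default 0.8).
#' @param min_dur_ms minimum bout duration, ms (default 250).
#' @param smooth_ms running-mean window, ms.
#' @return data.frame `t_start`, `t_end` (s, half-open), `duration_ms`,
#'   `label = "stop"`; zero rows if none.
#' @export
ball_stop_bouts <- function(velocity, frame_rate = 50, v_thresh = 0.8,
                            min_dur_ms = 250, smooth_ms = min_dur_ms) {
  w <- max(1L, as.integer(round(smooth_ms / 1000 * frame_rate)))
  v <- moving_average(velocity, w)
  runs <- true_runs(v < v_thresh)
  runs <- runs[runs$length * 1000 / frame_rate >= min_dur_ms, , drop = FALSE]
  data.frame(t_start = (runs$start - 1L) / frame_rate,
             t_end = runs$end / frame_rate,
             duration_ms = runs$length * 1000 / frame_rate,
             label = rep("stop", nrow(runs)))
}

#' Swing durations around a stimulation onset
#'
#' Before-onset statistic: the median duration of all swing phases completed
#' in the prestimulation period. After-onset statistic: the full duration of
#' the swing in progress at light onset, undefined (`NA`) when the onset
#' falls in stance.
#'
#' @param gait a `gait_trace`.
#' @param stim_onset stimulation onset, s from trace start.
#' @return list with `pre_median_ms` (`NA` if no completed pre-onset swing)
#'   and `continuing_swing_ms` (`NA` if onset falls in stance).
#' @export
swing_durations <- function(gait, stim_onset) {
  stopifnot(inherits(gait, "gait_trace"))
  fs <- gait$frame_rate
  n <- length(gait$phase)
  if (stim_onset < 0 || stim_onset > n / fs)
    stopf("stim_onset outside the trace")
  onset_frame <- floor(stim_onset * fs) + 1L  # frame containing the onset
  seg <- gait$segments
  sw <- seg[seg$label == "swing", , drop = FALSE]
  pre <- sw[sw$offset <= onset_frame, , drop = FALSE]
  pre_med <- if (nrow(pre)) stats::median(pre$duration_ms) else NA_real_
  cont <- NA_real_
  if (onset_frame <= n) {
    hit <- sw[sw$onset <= onset_frame & sw$offset > onset_frame, , drop = FALSE]
    if (nrow(hit)) cont <- hit$duration_ms[1L]
  }
  list(pre_median_ms = pre_med, continuing_swing_ms = cont)
}

#' Postural stability during grooming bouts
#'
#' For each (manually scored) grooming bout: the standard deviation of the
#' femur-tibia flexion angle of the supporting (non-grooming) legs — low
#' values mean the stance legs hold still — and the ball movement, defined
#' as the sum over the three rotation axes of the absolute rotational
#' velocity, averaged over the bout.
#'
#' @param angles numeric matrix (frames x legs) of femur-tibia angles of the
#'   non-grooming legs, degrees; a vector is treated as one leg.
#' @param bouts data.frame with `t_start`, `t_end` (s) of grooming bouts.
#' @param ball_rot numeric matrix (frames x 3) of rotational velocities.
#' @param frame_rate Hz.
#' @return data.frame per bout: `t_start`, `t_end`, `feti_sd_deg` (mean over
#'   legs of the per-leg sd; `NA` for bouts shorter than 2 frames) and
#'   `ball_movement`.
#' @export
grooming_stability <- function(angles, bouts, ball_rot, frame_rate = 200) {
  if (is.null(dim(angles))) angles <- matrix(angles, ncol = 1L)
  ball_rot <- as.matrix(ball_rot)
  n <- nrow(angles)
  if (any(bouts$t_start < 0) || any(bouts$t_end > n / frame_rate + 1e-9))
    stopf("bout(s) outside the recording")
  out <- bouts[c("t_start", "t_end")]
  out$feti_sd_deg <- NA_real_
  out$ball_movement <- NA_real_
  move <- rowSums(abs(ball_rot))
  for (b in seq_len(nrow(bouts))) {
    i0 <- floor(bouts$t_start[b] * frame_rate) + 1L
    i1 <- min(ceiling(bouts$t_end[b] * frame_rate), n)
    if (i1 - i0 + 1L >= 2L) {
      out$feti_sd_deg[b] <- mean(apply(angles[i0:i1, , drop = FALSE], 2,
                                       stats::sd))
    }
    if (i1 >= i0) out$ball_movement[b] <- mean(move[i0:i1])
  }
  out
}
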