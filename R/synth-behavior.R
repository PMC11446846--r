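# Synthetic behavior and imaging generators: gait on a sphere with planted
# swing/stance phases, arena trajectories with planted bouts, and
# fluorescence traces with planted activity-velocity coupling. Each
# generator is deterministic under its seed and returns a ground-truth
# manifest alongside the data.

#' Gait-generator specification
#'
#' Defaults mimic the tethered-fly regime: a 3 mm-radius air-supported ball
#' and 200 Hz pose sampling, with step cycles in the tens-of-milliseconds
#' range.
#'
#' @param ball_center sphere center `(x, y, z)`, mm.
#' @param ball_radius mm (default 3, i.e. a 6 mm ball).
#' @param frame_rate Hz (default 200).
#' @param duration_s recording length, s.
#' @param legs character vector of leg names to generate.
#' @param stance_ms,swing_ms phase durations of the step cycle, ms.
#' @param phase_offset_ms per-leg offset into the cycle, ms (recycled).
#' @param swing_clearance peak tip lift above the surface during swing, mm.
#' @param noise_sd isotropic positional noise sd, mm.
#' @return a `gait_spec` list.
#' @export
gait_spec <- function(ball_center = c(0, 0, 0), ball_radius = 3,
                      frame_rate = 200, duration_s = 2,
                      legs = c("FL", "FR", "ML", "MR", "HL", "HR"),
                      stance_ms = 60, swing_ms = 40,
                      phase_offset_ms = 0, swing_clearance = 0.3,
                      noise_sd = 0) {
  if (stance_ms < 5 || swing_ms < 5) stopf("phase durations must be >= 5 ms")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(ball_center = ball_center, ball_radius = ball_radius,
                 frame_rate = frame_rate, duration_s = duration_s,
                 legs = legs, stance_ms = stance_ms, swing_ms = swing_ms,
                 phase_offset_ms = rep_len(phase_offset_ms, length(legs)),
                 swing_clearance = swing_clearance, noise_sd = noise_sd),
            class = "gait_spec")
}

#' Generate synthetic gait on a sphere with known phases
#'
#' Tarsal tips sit on the ball surface during stance (plus noise) and lift
#' along their radial direction during swing, following a per-leg periodic
#' stance/swing plan. The ground truth lists the true sphere and every
#' phase segment per leg.
#'
#' @param spec a [gait_spec()].
#' @param seed integer seed.
#' @return list with `tips` (named list of n x 3 matrices per leg), `pose`
#'   (wide data.frame `frame` plus `<leg>_tip_<axis>` columns) and
#'   `truth` (list: `ball` with center/radius, `segments` data.frame `leg`,
#'   `onset`, `offset` half-open frames, `label`).
#' @export
synth_gait <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "gait_spec"))
  fs <- spec$frame_rate
  n <- as.integer(round(spec$duration_s * fs))
  cyc_ms <- spec$stance_ms + spec$swing_ms
  if (spec$noise_sd > 0 && spec$swing_clearance < 4 * spec$noise_sd)
    warning("swing clearance close to the noise floor: phases may be unrecoverable",
            call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))

  # fixed, well-spread anchor directions (lower hemisphere-ish)
  base_dirs <- rbind(c(1, 1, -1), c(-1, 1, -1), c(1, -1, -1),
                     c(-1, -1, -1), c(1, 0, -1), c(-1, 0, -1))
  tips <- list(); seg_all <- list()
  t_ms <- (seq_len(n) - 1L) * 1000 / fs
  for (li in seq_along(spec$legs)) {
    leg <- spec$legs[li]
    u <- base_dirs[((li - 1L) %% nrow(base_dirs)) + 1L, ]
    u <- u / sqrt(sum(u^2))
    ph <- (t_ms + spec$phase_offset_ms[li]) %% cyc_ms
    stance <- ph < spec$stance_ms
    # evaluate the lift at frame midpoints so every swing frame clears the
    # surface (the sine is zero at the exact phase boundaries)
    half_ms <- 500 / fs
    swing_frac <- ifelse(stance, 0,
                         (ph - spec$stance_ms + half_ms) / spec$swing_ms)
    lift <- spec$swing_clearance * sin(pi * swing_frac)
    radial <- spec$ball_radius + lift
    pts <- outer(radial, u) +
      matrix(spec$ball_center, n, 3, byrow = TRUE)
    if (spec$noise_sd > 0) {
      set.seed(substream_seed(seed, 2L, li))
      pts <- pts + matrix(stats::rnorm(3 * n, sd = spec$noise_sd), n, 3)
    }
    colnames(pts) <- c("x", "y", "z")
    tips[[leg]] <- pts
    seg <- phase_segments(stance, fs)
    seg$leg <- leg
    seg_all[[leg]] <- seg[c("leg", "onset", "offset", "label", "duration_ms")]
  }
  pose <- data.frame(frame = seq_len(n))
  for (leg in spec$legs)
    for (ax in c("x", "y", "z"))
      pose[[paste0(leg, "_tip_", ax)]] <- tips[[leg]][, ax]
  list(tips = tips, pose = pose,
       truth = list(ball = list(center = spec$ball_center,
                                radius = spec$ball_radius),
                    segments = do.call(rbind, c(seg_all,
                                                make.row.names = FALSE)),
                    frame_rate = fs, seed = as.integer(seed)))
}

#' Arena-trajectory specification
#'
#' @param plan data.frame with `behavior` (`walk`, `stop`, `pivot` or
#'   `approach`), `duration_s`, `speed` (mm/s) and `ang_deg_s` (signed
#'   heading rate, deg/s); executed in order.
#' @param frame_rate Hz (default 30).
#' @param start `(x, y)` start position, mm.
#' @param heading0 initial heading, degrees.
#' @param blob_center target of `approach` segments, mm.
#' @param noise_sd positional noise sd, mm.
#' @return a `track_spec` list.
#' @export
track_spec <- function(plan, frame_rate = 30, start = c(0, 0),
                       heading0 = 0, blob_center = c(15, 0),
                       noise_sd = 0) {
  stopifnot(all(c("behavior", "duration_s", "speed", "ang_deg_s")
                %in% names(plan)))
  if (any(plan$duration_s <= 0)) stopf("plan durations must be > 0")
  structure(list(plan = plan, frame_rate = frame_rate, start = start,
                 heading0 = heading0, blob_center = blob_center,
                 noise_sd = noise_sd),
            class = "track_spec")
}

#' Generate a synthetic arena trajectory with planted bouts
#'
#' Integrates the segment plan into a planar path: `walk` moves along the
#' current heading, `stop` freezes in place, `pivot` spins with minimal
#' translation, `approach` heads toward the blob center. The ground truth
#' lists each planned episode with its start/end time and label.
#'
#' @param spec a [track_spec()].
#' @param seed integer seed (used for the positional noise).
#' @return list with `track` (data.frame `frame`, `t`, `x`, `y`, `heading`,
#'   `behavior`) and `truth` (data.frame `label`, `t_start`, `t_end`).
#' @export
synth_track <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "track_spec"))
  fs <- spec$frame_rate
  dt <- 1 / fs
  n_seg <- nrow(spec$plan)
  n_frames <- sum(as.integer(round(spec$plan$duration_s * fs)))
  x <- numeric(n_frames); y <- numeric(n_frames)
  h <- numeric(n_frames); beh <- character(n_frames)
  cx <- spec$start[1]; cy <- spec$start[2]; ch <- spec$heading0
  f <- 0L
  truth <- data.frame(label = spec$plan$behavior,
                      t_start = NA_real_, t_end = NA_real_)
  for (s in seq_len(n_seg)) {
    sg <- spec$plan[s, ]
    nf <- as.integer(round(sg$duration_s * fs))
    truth$t_start[s] <- f * dt
    truth$t_end[s] <- (f + nf) * dt
    for (i in seq_len(nf)) {
      speed <- switch(sg$behavior, stop = 0, sg$speed)
      ang <- switch(sg$behavior, stop = 0, walk = sg$ang_deg_s,
                    pivot = sg$ang_deg_s, approach = 0)
      if (sg$behavior == "approach") {
        ch <- atan2(spec$blob_center[2] - cy, spec$blob_center[1] - cx) *
          180 / pi
      } else {
        ch <- ch + ang * dt
      }
      cx <- cx + speed * dt * cos(ch * pi / 180)
      cy <- cy + speed * dt * sin(ch * pi / 180)
      f <- f + 1L
      x[f] <- cx; y[f] <- cy; h[f] <- ch %% 360; beh[f] <- sg$behavior
    }
  }
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(seed, 3L))
    x <- x + stats::rnorm(n_frames, sd = spec$noise_sd)
    y <- y + stats::rnorm(n_frames, sd = spec$noise_sd)
  }
  list(track = data.frame(frame = seq_len(n_frames),
                          t = (seq_len(n_frames) - 1L) * dt,
                          x = x, y = y, heading = h, behavior = beh),
       truth = truth)
}

#' Fluorescence-trace specification
#'
#' @param duration_s recording length, s.
#' @param behavior_rate behavior sampling rate, Hz (default 50).
#' @param imaging_rate imaging rate, Hz (default 5).
#' @param lag_s planted lag of activity behind the reference, s.
#' @param gain planted coupling gain (0 for uncoupled traces).
#' @param kernel_tau calcium-kernel time constant, s.
#' @param noise_sd channel noise sd (fraction of baseline).
#' @param baseline_green,baseline_red channel baselines, a.u.
#' @return a `trace_spec` list.
#' @export
trace_spec <- function(duration_s = 60, behavior_rate = 50,
                       imaging_rate = 5, lag_s = 0.4, gain = 1,
                       kernel_tau = 0.3, noise_sd = 0.01,
                       baseline_green = 100, baseline_red = 200) {
  if (kernel_tau <= 0) stopf("kernel_tau must be > 0")
  structure(list(duration_s = duration_s, behavior_rate = behavior_rate,
                 imaging_rate = imaging_rate, lag_s = lag_s, gain = gain,
                 kernel_tau = kernel_tau, noise_sd = noise_sd,
                 baseline_green = baseline_green,
                 baseline_red = baseline_red),
            class = "trace_spec")
}

#' Generate synthetic two-channel traces with planted coupling
#'
#' Builds a smooth, non-negative reference velocity series, convolves its
#' lagged copy with an exponential calcium kernel and scales by the gain to
#' form the green (calcium-sensitive) channel; the red channel carries the
#' baseline only. Both channels receive independent noise. Channels are
#' emitted on the imaging clock (block-averaged), the reference on the
#' behavior clock.
#'
#' @param spec a [trace_spec()].
#' @param seed integer seed.
#' @return list with `green`, `red` (imaging clock), `reference` (behavior
#'   clock) and `truth` (lag_s, gain, rates).
#' @export
synth_traces <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "trace_spec"))
  fs <- spec$behavior_rate
  n <- as.integer(round(spec$duration_s * fs))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 4L))
  # smooth positive reference: low-pass filtered noise, rectified
  raw <- stats::rnorm(n)
  smooth_w <- as.integer(round(0.5 * fs))
  ref <- pmax(moving_average(raw, smooth_w), 0) * 10  # mm/s scale
  lag_n <- as.integer(round(spec$lag_s * fs))
  lagged <- c(numeric(lag_n), ref)[seq_len(n)]
  # exponential calcium kernel, unit area
  kt <- seq(0, 5 * spec$kernel_tau, by = 1 / fs)
  kern <- exp(-kt / spec$kernel_tau)
  kern <- kern / sum(kern)
  conv <- stats::filter(c(lagged, numeric(length(kern))), kern,
                        sides = 1)[seq_len(n)]
  conv[is.na(conv)] <- 0
  green_hi <- spec$baseline_green * (1 + spec$gain * conv / 10)
  red_hi <- rep(spec$baseline_red, n)
  green_hi <- green_hi + stats::rnorm(n, sd = spec$noise_sd *
                                        spec$baseline_green)
  red_hi <- red_hi + stats::rnorm(n, sd = spec$noise_sd *
                                    spec$baseline_red)
  fac <- fs / spec$imaging_rate
  if (abs(fac - round(fac)) > 1e-9)
    stopf("behavior_rate must be an integer multiple of imaging_rate")
  list(green = block_average(green_hi, fac),
       red = block_average(red_hi, fac),
       reference = ref,
       truth = list(lag_s = spec$lag_s, gain = spec$gain,
                    behavior_rate = fs, imaging_rate = spec$imaging_rate,
                    seed = as.integer(seed)))
}
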