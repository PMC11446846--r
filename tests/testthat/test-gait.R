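# Sphere fitting, swing/stance classification with the short-phase filter,
# joint angles, ball stop bouts, swing durations and grooming stability.

sphere_cloud <- function(center, radius, n = 200, seed = 1, noise_sd = 0) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * radius + matrix(center, n, 3, byrow = TRUE)
  if (noise_sd > 0) pts <- pts + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
  pts
}

test_that("sphere fit recovers noiseless parameters to numerical precision", {
  pts <- sphere_cloud(c(1, 2, 3), 3)
  fit <- fit_ball(pts)
  expect_lt(max(abs(fit$center - c(1, 2, 3))), 1e-6)
  expect_lt(abs(fit$radius - 3), 1e-6)
  expect_lt(fit$rms_residual, 1e-9)
  # agrees with the one-shot algebraic oracle
  alg <- oracle_sphere(pts)
  expect_lt(max(abs(fit$center - alg$center)), 1e-6)
})

test_that("sphere fit under noise: small radius error, oracle consistency", {
  errs <- vapply(1:100, function(s) {
    pts <- sphere_cloud(c(-1, 0.5, 2), 3, n = 300, seed = s,
                        noise_sd = 0.01)
    abs(fit_ball(pts)$radius - 3)
  }, numeric(1))
  expect_lt(max(errs), 0.05)

  pts <- sphere_cloud(c(0, 0, 0), 3, n = 300, seed = 7, noise_sd = 0.01)
  fit <- fit_ball(pts); alg <- oracle_sphere(pts)
  expect_lt(sqrt(sum((fit$center - alg$center)^2)), 0.01)
  # the geometric fit cannot be worse than the algebraic start
  rms <- function(c0, r0) sqrt(mean((sqrt(rowSums(
    (pts - matrix(c0, nrow(pts), 3, byrow = TRUE))^2)) - r0)^2))
  expect_lte(fit$rms_residual, rms(alg$center, alg$radius) + 1e-12)
})

test_that("degenerate clouds are rejected", {
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(fit_ball(flat), "coplanar|degenerate")
  expect_error(fit_ball(flat[1:3, ]), "at least 4")
})

test_that("gait classification recovers planted phases exactly", {
  # 20 ms phases at 200 Hz: 4-frame blocks
  stance <- rep(rep(c(TRUE, FALSE), 10), each = 4)
  gt <- gait_from_phases(stance, min_phase_ms = 10)
  expect_identical(gt$phase == "stance", stance)
  seg <- gt$segments
  expect_equal(nrow(seg), 20)
  expect_true(all(seg$duration_ms == 20))
  # all tips on the surface -> a single stance segment
  all_st <- gait_from_phases(rep(TRUE, 50))
  expect_equal(nrow(all_st$segments), 1)
  expect_equal(all_st$segments$label, "stance")
})

test_that("phases shorter than the minimum are filtered out", {
  # 5 ms lift-off blip (1 frame at 200 Hz) inside a long stance
  stance <- rep(TRUE, 100)
  stance[50] <- FALSE
  gt <- gait_from_phases(stance, min_phase_ms = 10)
  expect_equal(nrow(gt$segments), 1)
  expect_equal(gt$segments$label, "stance")

  # adversarial alternation of short blips: nothing below 10 ms survives
  set.seed(42)
  for (rep_i in 1:20) {
    stance <- rep(sample(c(TRUE, FALSE), 40, replace = TRUE),
                  times = sample(1:6, 40, replace = TRUE))
    gt <- gait_from_phases(stance, min_phase_ms = 10)
    expect_true(all(gt$segments$duration_ms >= 10))
    # segments must still tile the trace without overlap
    expect_equal(gt$segments$onset[1], 1)
    expect_equal(gt$segments$offset[nrow(gt$segments)], length(stance) + 1)
    if (nrow(gt$segments) > 1)
      expect_true(all(gt$segments$onset[-1] ==
                        head(gt$segments$offset, -1)))
  }
})

test_that("flexion angle geometry", {
  expect_equal(flexion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(flexion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  expect_equal(flexion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 135)
  expect_error(flexion_angle(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "zero-length")
  # vectorized over frames
  prox <- rbind(c(0, 0, 0), c(0, 0, 0))
  joint <- rbind(c(1, 0, 0), c(1, 0, 0))
  dist <- rbind(c(2, 0, 0), c(1, 1, 0))
  expect_equal(flexion_angle(prox, joint, dist), c(180, 90))
})

test_that("ball stop bouts: duration floor and ground-truth recovery", {
  fs <- 50
  expect_equal(nrow(ball_stop_bouts(rep(0, fs), fs)), 1)
  expect_equal(ball_stop_bouts(rep(0, fs), fs)$duration_ms, 1000)
  # 100 ms sub-threshold dip -> no bout
  v <- c(rep(5, 50), rep(0, 5), rep(5, 50))
  expect_equal(nrow(ball_stop_bouts(v, fs)), 0)
  # planted bouts, no smoothing: onsets/offsets exact
  v2 <- c(rep(5, 40), rep(0.2, 30), rep(6, 50), rep(0.1, 20), rep(4, 30))
  b <- ball_stop_bouts(v2, fs, smooth_ms = 1000 / fs)
  expect_equal(b$t_start, c(40, 120) / fs)
  expect_equal(b$t_end, c(70, 140) / fs)
  # with the default 250 ms running mean every bout still meets the floor
  set.seed(9)
  for (i in 1:20) {
    v3 <- abs(rnorm(500, mean = sample(c(0.2, 2), 1), sd = 1))
    bb <- ball_stop_bouts(v3, fs)
    if (nrow(bb)) expect_true(all(bb$duration_ms >= 250))
  }
})

test_that("swing durations around stimulation onset", {
  fs <- 200
  # swings of 40, 50, 60 ms then stance, onset at 0.5 s
  stance <- c(rep(c(rep(FALSE, 8), rep(TRUE, 4)), 1),   # 40 ms swing
              rep(FALSE, 10), rep(TRUE, 4),             # 50 ms swing
              rep(FALSE, 12), rep(TRUE, 60))            # 60 ms swing
  gt <- gait_from_phases(stance)
  sd1 <- swing_durations(gt, 0.45)
  expect_equal(sd1$pre_median_ms, 50)
  expect_true(is.na(sd1$continuing_swing_ms))  # onset mid-stance
  # onset 10 ms into an 80 ms swing -> continuing duration 80 ms
  stance2 <- c(rep(TRUE, 40), rep(FALSE, 16), rep(TRUE, 40))
  gt2 <- gait_from_phases(stance2)
  sd2 <- swing_durations(gt2, (40 + 2) / fs)
  expect_equal(sd2$continuing_swing_ms, 80)
  expect_true(is.na(sd2$pre_median_ms))  # no completed pre-onset swing
})

test_that("grooming stability: constant angles, stationary ball, sinusoid sd", {
  fs <- 200
  n <- 2000
  bouts <- data.frame(t_start = c(0.5, 5), t_end = c(4.5, 9))
  const_ang <- matrix(90, n, 2)
  rot0 <- matrix(0, n, 3)
  g <- grooming_stability(const_ang, bouts, rot0, fs)
  expect_equal(g$feti_sd_deg, c(0, 0))
  expect_equal(g$ball_movement, c(0, 0))
  # sinusoid amplitude A over many cycles: sd -> A / sqrt(2) within 1%
  A <- 20
  ang <- 90 + A * sin(2 * pi * 10 * (seq_len(n) - 1) / fs)
  g2 <- grooming_stability(ang, data.frame(t_start = 0, t_end = n / fs),
                           rot0, fs)
  expect_lt(abs(g2$feti_sd_deg - A / sqrt(2)) / (A / sqrt(2)), 0.01)
  # ball movement sums absolute rotational speeds
  rot <- cbind(rep(1, n), rep(-2, n), rep(0.5, n))
  g3 <- grooming_stability(ang, data.frame(t_start = 0, t_end = 1), rot, fs)
  expect_equal(g3$ball_movement, 3.5)
  # sub-2-frame bout flagged
  g4 <- grooming_stability(ang, data.frame(t_start = 0, t_end = 0.004),
                           rot, fs)
  expect_true(is.na(g4$feti_sd_deg))
})
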