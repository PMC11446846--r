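# Arena kinematics, pivot/stop detection, trial metrics, preference index
# and food-zone quantification.

straight_track <- function(speed = 5, fs = 30, dur = 4, heading = 0) {
  n <- dur * fs
  data.frame(x = (seq_len(n) - 1) * speed / fs, y = 0,
             heading = rep(heading, n))
}

circle_track <- function(omega = 90, fs = 30, dur = 4, radius = 5) {
  n <- dur * fs
  th <- (seq_len(n) - 1) * omega / fs  # degrees
  data.frame(x = radius * cos(th * pi / 180),
             y = radius * sin(th * pi / 180),
             heading = (th + 90) %% 360)
}

test_that("kinematics: straight path, circular path, stationary fly", {
  k <- track_kinematics(straight_track(5), 30)
  expect_equal(unique(round(k$v_trans, 9)), 5)
  expect_equal(unique(k$v_ang), 0)
  expect_equal(k$rotation[nrow(k)], 0)

  # constant omega for T seconds: rotation = omega * T (heading wraps at 360)
  fs <- 30; dur <- 4; omega <- 90
  k2 <- track_kinematics(circle_track(omega, fs, dur), fs)
  expect_equal(unique(round(k2$v_ang, 6)), omega)
  expect_equal(k2$rotation[nrow(k2)], omega * (dur * fs - 1) / fs,
               tolerance = 1e-9)

  still <- data.frame(x = rep(1, 60), y = 2, heading = 33)
  k3 <- track_kinematics(still, 30)
  expect_true(all(k3$v_trans == 0 & k3$v_ang == 0 & k3$rotation == 0))

  bad <- straight_track(5); bad$t <- c(0, cumsum(runif(nrow(bad) - 1)))
  expect_error(track_kinematics(bad, 30), "uniform")
})

test_that("velocities are invariant to arena translation and rotation", {
  tr <- circle_track(120, 30, 3)
  k0 <- track_kinematics(tr, 30)
  th <- 35 * pi / 180
  tr2 <- data.frame(x = 7 + cos(th) * tr$x - sin(th) * tr$y,
                    y = -3 + sin(th) * tr$x + cos(th) * tr$y,
                    heading = (tr$heading + 35) %% 360)
  k1 <- track_kinematics(tr2, 30)
  expect_equal(k1$v_trans, k0$v_trans, tolerance = 1e-9)
  expect_equal(k1$v_ang, k0$v_ang, tolerance = 1e-9)
})

test_that("rotation is additive over adjacent windows", {
  set.seed(2)
  n <- 300
  tr <- data.frame(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
                   heading = (cumsum(rnorm(n, sd = 20))) %% 360)
  m <- trial_metrics(tr, onsets = c(1, 3), horizon = 2, frame_rate = 30)
  whole <- trial_metrics(tr, onsets = 1, horizon = 4, frame_rate = 30)
  expect_equal(sum(m$rotation), whole$rotation, tolerance = 1e-9)
  expect_equal(sum(m$distance), whole$distance, tolerance = 1e-9)
})

test_that("pivot detection: joint thresholds and frame-scan agreement", {
  fs <- 30
  v_ang <- c(rep(0, 30), rep(3 * 360, 30), rep(0, 30))
  v_trans_low <- rep(2, 90)
  p <- detect_pivots(v_trans_low, v_ang, fs, smooth_window = 1 / fs)
  expect_equal(nrow(p), 1)
  expect_equal(p$duration_ms, 1000)
  # high translation defeats the pivot
  p2 <- detect_pivots(rep(8, 90), v_ang, fs, smooth_window = 1 / fs)
  expect_equal(nrow(p2), 0)
  # randomized traces match the brute-force scanner
  for (s in 1:100) {
    set.seed(4000 + s)
    va <- abs(rnorm(200, 600, 300))
    vt <- abs(rnorm(200, 5, 3))
    got <- detect_pivots(vt, va, fs, smooth_window = 1 / fs)
    ref <- oracle_runs(va > 720 & vt < 5)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref))
      expect_equal(got$t_start, (ref$start - 1) / fs)
  }
})

test_that("stop detection honors thresholds and minimum run length", {
  fs <- 30
  s <- detect_stops(rep(0, 30), fs, "food_assay", smooth_window = 1 / fs)
  expect_equal(nrow(s), 1)
  expect_equal(s$duration_ms, 1000)
  # 8-frame dip is too short for the food-assay ten-frame rule
  v <- c(rep(5, 30), rep(0, 8), rep(5, 30))
  expect_equal(nrow(detect_stops(v, fs, "food_assay",
                                 smooth_window = 1 / fs)), 0)
  # planted bouts recovered exactly without smoothing
  v2 <- c(rep(6, 45), rep(0.5, 20), rep(6, 40), rep(1, 12), rep(6, 20))
  got <- detect_stops(v2, fs, "food_assay", smooth_window = 1 / fs)
  expect_equal(got$t_start, c(45, 105) / fs)
  expect_equal(got$duration_ms, c(20, 12) / fs * 1000)
  # freewalk variant uses its own threshold
  fw <- detect_stops(rep(1.2, 60), fs, "freewalk", smooth_window = 1 / fs)
  expect_equal(nrow(fw), 1)
  expect_equal(nrow(detect_stops(rep(1.8, 60), fs, "freewalk",
                                 smooth_window = 1 / fs)), 0)
})

test_that("trial metrics: closed-form distance and horizon scaling", {
  fs <- 30
  tr <- straight_track(5, fs, dur = 8)
  m <- trial_metrics(tr, onsets = 1, horizon = 2, frame_rate = fs)
  expect_equal(m$distance, 10, tolerance = 1e-9)
  expect_equal(m$rotation, 0)
  expect_false(m$truncated)
  # metrics scale linearly with the horizon on constant-velocity data
  m1 <- trial_metrics(tr, 1, horizon = 1, frame_rate = fs)
  m3 <- trial_metrics(tr, 1, horizon = 3, frame_rate = fs)
  expect_equal(m3$distance / m1$distance, 3, tolerance = 1e-9)
  # stationary -> zeros; over-long horizon flagged
  still <- data.frame(x = rep(0, 60), y = 0, heading = 0)
  m0 <- trial_metrics(still, 0.5, horizon = 10, frame_rate = fs)
  expect_equal(m0$distance, 0)
  expect_true(m0$truncated)
})

test_that("preference index from side labels", {
  expect_equal(preference_index(rep("sucrose", 90))$pi, 1)
  expect_equal(preference_index(rep(c("sucrose", "blank"), 45))$pi, 0)
  expect_equal(preference_index(c(rep("sucrose", 90),
                                  rep("blank", 30)))$pi, 0.5)
  expect_error(preference_index(rep(NA_character_, 10)), "no labeled")
  # time-weighted: invariant to frame-rate resampling
  side <- c(rep("sucrose", 30), rep("blank", 10))
  p30 <- preference_index(side, 30)$pi
  p60 <- preference_index(rep(side, each = 2), 60)$pi
  expect_equal(p30, p60)
})

test_that("food-zone metrics: geometry validation and planted stop", {
  fs <- 30
  cfg <- food_zone_config(blob_center = c(15, 0))
  # approach the blob then freeze for 4 s inside the zone
  plan <- data.frame(behavior = c("approach", "stop"),
                     duration_s = c(2, 4.5),
                     speed = c(8, 0), ang_deg_s = 0)
  st <- synth_track(track_spec(plan, frame_rate = fs, start = c(0, 0),
                               blob_center = c(15, 0)), seed = 1)
  fz <- food_zone_metrics(st$track, cfg, frame_rate = fs)
  expect_true(fz$entered)
  # encounter when within 3 mm of the blob: after ~1.5 s at 8 mm/s
  expect_equal(fz$encounter_frame, which(sqrt((st$track$x - 15)^2 +
                                                st$track$y^2) <= 3)[1])
  expect_gte(nrow(fz$stop_bouts), 1)
  expect_gt(max(fz$stop_bouts$duration_ms), 3000)
  expect_lt(fz$v_trans_in_zone, 3)
  # never entering -> empty flagged result; bad encounter frame -> error
  far <- data.frame(x = rep(0, 60), y = 0, heading = 0)
  fz0 <- food_zone_metrics(far, cfg, frame_rate = fs)
  expect_false(fz0$entered)
  expect_error(food_zone_metrics(st$track, cfg, encounter_frame = 2,
                                 frame_rate = fs), "inconsistent")
})
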