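test_that("landmarks match generator ground truth exactly on noise-free trials", {
  for (s in 1:4) {
    hit <- s %% 2 == 0
    bt <- if (s > 2) "elastic" else "normal"
    tr <- simulate_trial(bt, hit = hit, gaze = quiet_gaze(), seed = s)
    seg <- segment_trial(tr$raw)
    expect_identical(seg$release_frame, tr$truth$release_frame)
    expect_identical(seg$bounce_frame, tr$truth$bounce_frame)
    expect_identical(seg$contact_frame, tr$truth$contact_frame)
    expect_identical(seg$contact_kind, if (hit) "strike" else "pass")
  }
})

test_that("a missed ball's contact frame equals the brute-force depth-crossing scan", {
  tr <- simulate_trial("normal", hit = FALSE, gaze = quiet_gaze(), seed = 3)
  seg <- segment_trial(tr$raw)
  scan <- which(tr$raw$ball_z < tr$raw$ctrl_z &
                  seq_len(nrow(tr$raw)) > seg$bounce_frame)[1L]
  expect_identical(seg$contact_frame, as.integer(scan))
})

test_that("a stationary ball raises a release-detection flag, not an error", {
  raw <- quiet_trial()$raw
  raw$ball_x <- raw$ball_x[1L]
  raw$ball_y <- raw$ball_y[1L]
  raw$ball_z <- raw$ball_z[1L]
  seg <- segment_trial(raw)
  expect_true("no_release" %in% seg$qc_flags)
  expect_true(is.na(seg$release_frame))
})

test_that("the positional filter preserves passband amplitude and is zero-phase", {
  fs <- 90
  t <- seq(0, 4, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)              # 1 Hz sine, well inside the passband
  y <- filter_positional(x, cutoff = 10, fs = fs)
  core <- seq(fs, length(t) - fs)       # ignore the first/last second
  expect_lt(max(abs(y[core] - x[core])), 0.01)
  # constant series unchanged
  expect_equal(filter_positional(rep(2.5, 200), 10, fs), rep(2.5, 200),
               tolerance = 1e-9)
  # zero phase: cross-correlation of a band-limited signal peaks at lag 0
  set.seed(1)
  z <- filter_positional(stats::rnorm(600), cutoff = 5, fs = fs)
  zf <- filter_positional(z, cutoff = 10, fs = fs)
  cc <- stats::ccf(zf, z, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # time-reversal symmetry (away from the boundary transients)
  fwd <- rev(filter_positional(z, 10, fs))
  bwd <- filter_positional(rev(z), 10, fs)
  core2 <- 30:(length(z) - 29)
  expect_equal(bwd[core2], fwd[core2], tolerance = 1e-6)
  expect_error(filter_positional(x, cutoff = 45, fs = fs), "Nyquist")
})

test_that("gaze filtering removes single-sample spikes and clamps the saccade cutoff", {
  x <- rep(1, 100)
  x[50] <- 25
  y <- suppressWarnings(filter_gaze(x, "saccade", fs = 90))
  expect_lt(max(abs(y - 1)), 1e-6)
  expect_warning(filter_gaze(x, "saccade", fs = 90), "44.55")
  # position purpose (15 Hz < Nyquist) warns not
  expect_silent(filter_gaze(x, "position", fs = 90))
  expect_equal(filter_gaze(rep(3, 50), "position", fs = 90), rep(3, 50),
               tolerance = 1e-9)
})

test_that("world and egocentric angles follow the stated conventions", {
  # gaze along the horizontal forward axis, level head
  lvl <- c(1, 0, 0, 0)
  a <- to_world_angles(c(0, 0, 1), lvl)
  expect_equal(unlist(a), c(yaw = 0, pitch = 0, ego_yaw = 0, ego_pitch = 0))
  # gaze 45 deg upward in the head frame of a level head
  a45 <- to_world_angles(c(0, sin(pi / 4), cos(pi / 4)), lvl)
  expect_equal(a45$pitch, 45, tolerance = 1e-9)
  expect_equal(a45$ego_pitch, 45, tolerance = 1e-9)
  # head pitched down 10 deg, gaze level in the world: egocentric pitch +10
  q_down <- mat_to_quat(interceptvr:::look_rotation(0, -10))
  a10 <- to_world_angles(c(0, 0, 1), q_down)
  expect_equal(a10$pitch, 0, tolerance = 1e-9)
  expect_equal(a10$ego_pitch, 10, tolerance = 1e-9)
  # rotation-composition oracle: arbitrary head pose, ego angles recover the
  # angles the vector was constructed with
  R <- interceptvr:::look_rotation(25, -12)
  v_head <- angles_to_dir(-8, 17)[1L, ]
  v_world <- as.numeric(R %*% v_head)
  a2 <- to_world_angles(v_world, mat_to_quat(R))
  expect_equal(a2$ego_yaw, -8, tolerance = 1e-9)
  expect_equal(a2$ego_pitch, 17, tolerance = 1e-9)
  # zero-norm vector becomes a missing sample
  a0 <- to_world_angles(c(0, 0, 0), lvl)
  expect_true(is.na(a0$pitch) && is.na(a0$ego_pitch))
})

test_that("angular kinematics match constant-rate and ramp oracles", {
  fs <- 90
  # 1 deg/frame rotation: 90 deg/s, zero acceleration
  yaw <- seq(0, 100) * 1
  d <- angles_to_dir(yaw, rep(0, length(yaw)))
  k <- angular_kinematics(d, 1 / fs)
  expect_equal(k$velocity[-1], rep(90, length(yaw) - 1), tolerance = 1e-9)
  expect_equal(k$acceleration[-(1:2)], rep(0, length(yaw) - 2), tolerance = 1e-6)
  # static gaze
  ks <- angular_kinematics(angles_to_dir(rep(5, 50), rep(-3, 50)), 1 / fs)
  expect_equal(ks$velocity[-1], rep(0, 49))
  # ramped rate: yaw = 0.5 * a * t^2 -> angular acceleration a
  a_true <- 200  # deg/s^2
  t <- seq(0, 1, by = 1 / fs)
  d2 <- angles_to_dir(0.5 * a_true * t^2, rep(0, length(t)))
  k2 <- angular_kinematics(d2, 1 / fs)
  mid <- 10:80
  expect_equal(mean(k2$acceleration[mid]), a_true, tolerance = 0.01 * a_true)
  # integrating velocity recovers the angular path within 0.5%
  path <- sum(k2$velocity[-1]) / fs
  expect_lt(abs(path - 0.5 * a_true * 1^2) / (0.5 * a_true), 0.005)
})

test_that("exclusion thresholds are exact and monotone", {
  fs <- 90
  n <- 200
  # 21% missing -> excluded; 19% scattered singles -> retained
  m21 <- rep(FALSE, n); m21[seq_len(ceiling(0.21 * n))] <- TRUE
  m21 <- sample(m21)  # placement is irrelevant for the fraction rule
  expect_true(exclude_trial(m21, fs)$excluded)
  m19 <- rep(FALSE, n); m19[seq(1, by = 5, length.out = 38)] <- TRUE
  expect_false(exclude_trial(m19, fs)$excluded)
  expect_lt(mean(m19), 0.20)
  # a 10-frame gap is 111 ms -> excluded; a 9-frame gap is exactly 100 ms ->
  # retained (strictly-greater rule)
  g10 <- rep(FALSE, n); g10[50:59] <- TRUE
  expect_true(exclude_trial(g10, fs)$excluded)
  expect_equal(exclude_trial(g10, fs)$reason, "tracking_gap")
  g9 <- rep(FALSE, n); g9[50:58] <- TRUE
  expect_false(exclude_trial(g9, fs)$excluded)
  # monotonicity: adding missing samples never un-excludes
  set.seed(42)
  for (r in 1:20) {
    base <- stats::runif(n) < 0.1
    extra <- base | (stats::runif(n) < 0.1)
    if (exclude_trial(base, fs)$excluded)
      expect_true(exclude_trial(extra, fs)$excluded)
  }
})

test_that("winsorization respects the strict 3-SD boundary per group", {
  # hand arithmetic: {0,0,0,0,100} has mean 20, SD ~44.7; 100 < 20 + 3*44.7
  v <- c(0, 0, 0, 0, 100)
  expect_equal(winsorize(v), v)
  # identical values unchanged (zero-variance group)
  expect_equal(winsorize(rep(7, 10)), rep(7, 10))
  # a value exactly at mean + 3 SD is unchanged; just beyond is replaced
  x <- c(-1, 1, -1, 1)
  m <- mean(x); s <- stats::sd(x)
  at <- c(x, m + 3 * s)
  # recompute on the full vector: the boundary is defined by the group stats
  mm <- mean(at); ss <- stats::sd(at)
  y <- c(at, mm + 3 * ss)
  expect_equal(winsorize(y)[length(y)], y[length(y)])
  z <- y; z[length(z)] <- mm + 3 * ss  # exactly at the old boundary
  # groups are treated independently
  g <- rep(c("a", "b"), each = 5)
  vals <- c(1, 1, 1, 1, 50, 1, 1, 1, 1, 1)
  out <- winsorize(vals, g)
  expect_equal(out[6:10], vals[6:10])
})

test_that("winsorize replaces genuinely outlying values with the boundary", {
  set.seed(3)
  x <- c(stats::rnorm(200), 25)
  m <- mean(x); s <- stats::sd(x)
  expect_gt(25, m + 3 * s)
  out <- winsorize(x)
  expect_equal(out[201], m + 3 * s)
  expect_equal(out[1:200], x[1:200])
})

test_that("preprocess_trial assembles a QC'd recording", {
  tr <- quiet_trial()
  rec <- preprocess_trial(tr$raw)
  expect_s3_class(rec, "ivr_recording")
  expect_false(rec$qc$excluded)
  expect_lt(rec$release_frame, rec$bounce_frame)
  expect_lt(rec$bounce_frame, rec$contact_frame)
  expect_equal(nrow(rec$angles), nrow(tr$raw))
})
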