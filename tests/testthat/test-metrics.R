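test_that("bounce fixation selection follows the containment-then-latest rule", {
  fx <- data.frame(onset = c(10L, 40L, 80L), offset = c(25L, 60L, 100L))
  # spanning fixation wins
  expect_equal(bounce_fixation(fx, 50L)$onset, 40L)
  # two fixations end pre-bounce: the later one
  expect_equal(bounce_fixation(fx, 70L)$onset, 40L)
  expect_equal(bounce_fixation(fx, 120L)$onset, 80L)
  # none before the bounce
  expect_null(bounce_fixation(fx, 5L))
  expect_null(bounce_fixation(fx[0, ], 50L))
})

test_that("bounce-fixation metrics average egocentric pitch over the half-open window", {
  ego <- rep(10, 100)
  fix <- data.frame(onset = 20L, offset = 38L)   # 18 frames at 90 Hz
  bm <- bounce_fixation_metrics(fix, ego, fs = 90)
  expect_equal(bm$pitch, 10)
  expect_equal(bm$duration, 0.2, tolerance = 1e-9)
  # linear ramp 8 -> 12 averages to 10
  ego2 <- rep(NA_real_, 100)
  ego2[20:37] <- seq(8, 12, length.out = 18)
  expect_equal(bounce_fixation_metrics(fix, ego2, fs = 90)$pitch, 10)
})

test_that("generator bounce fixation is measured at its configured pitch", {
  for (off in c(8, 10)) {
    tr <- simulate_trial("normal", hit = TRUE,
                         gaze = quiet_gaze(bounce_fixation_pitch_offset = off),
                         seed = 2)
    rec <- preprocess_trial(tr$raw)
    m <- trial_metrics(rec)
    expect_equal(m$bounce_fix_pitch, off, tolerance = 0.1)
    # ground-truth oracle on the injected window is exact
    ev <- tr$truth$gaze_events
    fix <- ev[ev$role == "bounce_fixation", ]
    ang <- to_world_angles(
      as.matrix(tr$raw[fix$onset:(fix$offset - 1L),
                       c("gaze_dir_x", "gaze_dir_y", "gaze_dir_z")]),
      as.matrix(tr$raw[fix$onset:(fix$offset - 1L),
                       c("head_qw", "head_qx", "head_qy", "head_qz")]))
    expect_equal(mean(ang$ego_pitch), off, tolerance = 1e-9)
  }
})

test_that("peak swing velocity matches constant-rate and analytic-bell oracles", {
  fs <- 90
  # constant 2 m/s approach along +z toward an aim point
  n <- 60
  ctrl <- cbind(0, 0, seq(0, by = 2 / fs, length.out = n))
  res <- peak_swing_velocity(ctrl, n, aim = c(0, 0, ctrl[n, 3] + 0.01), fs = fs)
  expect_equal(res$peak, 2, tolerance = 1e-9)
  # bell profile v(t) = 3 sin(pi t / T): discrete max within 1% of 3
  T <- 0.5
  t <- seq(0, T, by = 1 / fs)
  s <- 3 * T / pi * (1 - cos(pi * t / T))   # integral of the bell
  ctrl2 <- cbind(0, 0, s)
  res2 <- peak_swing_velocity(ctrl2, length(t),
                              aim = c(0, 0, max(s) + 0.01), fs = fs)
  expect_lt(abs(res2$peak - 3) / 3, 0.01)
  # generator identity: configured peak with no noise
  tr <- quiet_trial()
  rec <- preprocess_trial(tr$raw)
  m <- trial_metrics(rec)
  expect_equal(m$peak_swing_velocity, tr$truth$peak_swing_speed,
               tolerance = 0.01)
})

test_that("a swing that never approaches yields a flagged missing peak", {
  n <- 60
  ctrl <- cbind(0, 0, seq(1, by = -0.01, length.out = n))  # backing away
  res <- peak_swing_velocity(ctrl, n, aim = c(0, 0, 5), fs = 90)
  expect_true(is.na(res$peak))
  expect_equal(res$flag, "no_foreswing")
  # constant position: zero peak, not a failure
  still <- matrix(0.5, n, 3)
  res0 <- peak_swing_velocity(still, n, aim = c(0, 0, 5), fs = 90)
  expect_equal(res0$peak, 0)
})

test_that("interception tests sphere against the inflated oriented box inclusively", {
  cfg <- physics_config()
  quat <- matrix(c(1, 0, 0, 0), 3, 4, byrow = TRUE)
  ctrl <- matrix(0, 3, 3)
  # straight through the centre
  thru <- rbind(c(0, 0, 1), c(0, 0, 0), c(0, 0, -1))
  expect_true(interception_outcome(thru, ctrl, quat, cfg))
  # passing 1 m wide
  wide <- rbind(c(1, 0, 1), c(1, 0, 0), c(1, 0, -1))
  expect_false(interception_outcome(wide, ctrl, quat, cfg))
  # grazing: sphere centre exactly at half-extent + radius along x
  graze_x <- cfg$racquet_extent[1] / 2 + cfg$ball_diameter / 2
  graze <- rbind(c(graze_x, 0, 1), c(graze_x, 0, 0), c(graze_x, 0, -1))
  expect_true(interception_outcome(graze, ctrl, quat, cfg))
  beyond <- graze + matrix(c(1e-3, 0, 0), 3, 3, byrow = TRUE)
  expect_false(interception_outcome(beyond, ctrl, quat, cfg))
  # the box rotates with the controller: a point 0.25 m deep along z is
  # outside the flat racquet but inside one yawed 90 deg (wide face along z)
  Rq <- mat_to_quat(interceptvr:::rot_y(90))
  quat_r <- matrix(Rq, 3, 4, byrow = TRUE)
  deep <- rbind(c(0, 0, 0.25))
  expect_false(interception_outcome(deep, ctrl[1, , drop = FALSE],
                                    quat[1, , drop = FALSE], cfg))
  expect_true(interception_outcome(deep, ctrl[1, , drop = FALSE],
                                   quat_r[1, , drop = FALSE], cfg))
})

test_that("interception metrics reproduce the generator's ground truth", {
  for (s in 1:4) {
    hit <- s %% 2 == 0
    tr <- simulate_trial("normal", hit = hit, gaze = quiet_gaze(), seed = s)
    rec <- preprocess_trial(tr$raw)
    expect_identical(trial_metrics(rec)$intercepted, hit)
  }
})

test_that("prior errors count consecutive preceding misses, capped and reset", {
  trials <- data.frame(
    participant = "P01", block = 1L, trial = 1:8,
    feedback_call = c("hit", "miss", "miss", "hit", "miss", "miss",
                      "miss", "miss"),
    hit_truth = 1L)
  probes <- data.frame(participant = "P01", block = 1L, trial = 4L,
                       pof = 2, cof = 3, anxiety = 5)
  tab <- assemble_analysis_table(trials, probes)
  tt <- tab$trial_table
  # calls: [hit, miss, miss, hit, ...] -> trial 4 has 2 preceding misses
  expect_equal(tt$prior_errors, c(0L, 0L, 1L, 2L, 0L, 1L, 2L, 3L))
  # six consecutive misses cap at 4
  trials2 <- data.frame(participant = "P01", block = 1L, trial = 1:7,
                        feedback_call = c(rep("miss", 6L), "hit"),
                        hit_truth = 1L)
  tab2 <- assemble_analysis_table(trials2, probes[0, ])
  expect_equal(tab2$trial_table$prior_errors, c(0L, 1L, 2L, 3L, 4L, 4L, 4L))
  # carried anxiety: NA before the first probe, then the latest value
  expect_true(all(is.na(tt$anxiety[1:4])))
  expect_true(all(tt$anxiety[5:8] == 5))
})

test_that("carried reports cross block boundaries in completed order", {
  trials <- expand.grid(trial = 1:3, block = 1:2)
  trials$participant <- "P01"
  trials$feedback_call <- "hit"
  trials$hit_truth <- 1L
  probes <- data.frame(participant = "P01", block = c(1L, 2L),
                       trial = c(2L, 2L), pof = c(1, 2), cof = c(1, 2),
                       anxiety = c(3, 7))
  tt <- assemble_analysis_table(trials, probes)$trial_table
  expect_true(all(is.na(tt$anxiety[tt$block == 1 & tt$trial <= 2])))
  expect_equal(tt$anxiety[tt$block == 1 & tt$trial == 3], 3)
  expect_equal(tt$anxiety[tt$block == 2 & tt$trial <= 2], c(3, 3))
  expect_equal(tt$anxiety[tt$block == 2 & tt$trial == 3], 7)
})

test_that("metrics are insensitive to row order after time-sorting", {
  tr <- quiet_trial()
  rec1 <- preprocess_trial(tr$raw)
  m1 <- trial_metrics(rec1)
  shuffled <- tr$raw[sample(nrow(tr$raw)), ]
  sorted <- shuffled[order(shuffled$time_s), ]
  rownames(sorted) <- NULL
  m2 <- trial_metrics(preprocess_trial(sorted))
  expect_equal(m1, m2)
})
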