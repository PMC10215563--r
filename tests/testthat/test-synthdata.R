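test_that("generated gaze events cover the trial and include the full sequence", {
  b <- ball_trajectory("normal", outcome = "hit")
  g <- generate_gaze(b, quiet_gaze(), seed = 3)
  ev <- g$events
  expect_gte(nrow(ev), 3L)
  expect_setequal(unique(ev$class), c("fixation", "pursuit", "saccade"))
  # contiguous coverage of every frame
  expect_equal(ev$onset[1L], 1L)
  expect_equal(ev$offset[nrow(ev)], nrow(b$series) + 1L)
  expect_equal(ev$onset[-1L], ev$offset[-nrow(ev)])
  # the predictive saccade ends where the bounce fixation starts, before the
  # bounce itself
  fix <- ev[ev$role == "bounce_fixation", ]
  expect_lt(fix$onset, b$bounce_frame)
  expect_gt(fix$offset, b$bounce_frame)
})

test_that("bounce-fixation egocentric pitch equals the configured offset exactly", {
  b <- ball_trajectory("normal", outcome = "hit")
  for (off in c(5, 10)) {
    g <- generate_gaze(b, quiet_gaze(bounce_fixation_pitch_offset = off))
    fix <- g$events[g$events$role == "bounce_fixation", ]
    idx <- fix$onset:(fix$offset - 1L)
    ang <- to_world_angles(g$dir[idx, ], g$head$quat)
    expect_equal(mean(ang$ego_pitch), off, tolerance = 1e-9)
  }
})

test_that("pursuit at gain 1 matches the ball's angular velocity", {
  b <- ball_trajectory("normal", outcome = "hit")
  g <- generate_gaze(b, quiet_gaze(pursuit_gain = 1))
  ev <- g$events
  pur <- ev[ev$role == "pre_bounce_pursuit", ]
  idx <- (pur$onset + 2L):(pur$offset - 1L)
  dt <- 1 / 90
  gk <- angular_kinematics(g$dir, dt)
  eye <- g$head$position
  bdir <- cbind(b$series$x - eye[1], b$series$y - eye[2], b$series$z - eye[3])
  bk <- angular_kinematics(bdir, dt)
  # finite-difference oracle on the ball track
  expect_equal(gk$velocity[idx], bk$velocity[idx], tolerance = 0.02)
})

test_that("dropout inserts missing runs and jitter perturbs fixations", {
  b <- ball_trajectory("normal", outcome = "hit")
  g <- generate_gaze(b, gaze_config(dropout_rate = 0.02, dropout_run_length = 3,
                                    fixation_jitter_sd = 0.2), seed = 10)
  expect_true(any(!g$valid))
  r <- rle(!g$valid)
  expect_gte(max(r$lengths[r$values]), 3L)
  expect_true(all(g$dir[!g$valid, ] == 0))
})

test_that("swing peak speed is the configured identity, and zero swings are still", {
  b <- ball_trajectory("normal", outcome = "hit")
  sw <- generate_swing(b, swing_config(peak_speed = 4))
  v <- diff(sw$pos) * 90
  speed <- sqrt(rowSums(v^2))
  expect_equal(max(speed), sw$peak_speed, tolerance = 1e-9)
  expect_equal(sw$peak_speed, 4, tolerance = 0.05)  # grid-rounded duration
  # hand arrives at the aim point exactly at contact
  expect_equal(as.numeric(sw$pos[sw$contact_frame, ]), sw$aim, tolerance = 1e-12)
  sw0 <- generate_swing(b, swing_config(peak_speed = 0))
  expect_equal(max(abs(diff(sw0$pos))), 0)
})

test_that("noisy swing's filtered peak stays within 5% of the analytic maximum", {
  b <- ball_trajectory("normal", outcome = "hit")
  sw <- generate_swing(b, swing_config(peak_speed = 4, noise_sd = 0.002),
                       seed = 2)
  filt <- filter_positional(sw$pos, cutoff = 10, fs = 90)
  res <- peak_swing_velocity(filt, sw$contact_frame, aim = sw$aim, fs = 90)
  expect_lt(abs(res$peak - sw$peak_speed) / sw$peak_speed, 0.05)
})

test_that("a backswing away from the ball precedes the foreswing", {
  b <- ball_trajectory("normal", outcome = "hit")
  sw <- generate_swing(b, swing_config())
  v <- diff(sw$pos) * 90
  to_aim <- matrix(sw$aim, nrow(v), 3L, byrow = TRUE) - sw$pos[-nrow(sw$pos), ]
  comp <- rowSums(v * to_aim / sqrt(rowSums(to_aim^2)))
  pre <- comp[seq_len(sw$foreswing_onset - 2L)]
  expect_lt(min(pre), 0)                      # motion away from the ball
  fore <- comp[(sw$foreswing_onset):(sw$contact_frame - 2L)]
  expect_true(all(fore > -1e-9))
})

test_that("session bundles are deterministic and follow the design arithmetic", {
  cfg <- load_config()
  cfg$session <- session_config(n_trials = 12L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_session(cfg, seed = 9, participants = 1, out_dir = d1,
                   keep_series = FALSE)
  simulate_session(cfg, seed = 9, participants = 1, out_dir = d2,
                   keep_series = FALSE)
  files <- list.files(d1, recursive = TRUE)
  expect_length(files, 4L * 12L + 2L)          # trials + manifest + probes
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 9e6),
                     readBin(file.path(d2, f), "raw", 9e6))
  man <- read_manifest(d1)
  expect_equal(nrow(man$trials), 48L)
  expect_equal(nrow(man$probes), 24L)
  # every block holds each 2x2 cell once
  cells <- unique(man$trials[, c("block", "pressure", "feedback")])
  expect_equal(nrow(cells), 4L)
  expect_equal(nrow(unique(cells[, c("pressure", "feedback")])), 4L)
  # ball-type frequency close to p(normal) = 0.67 within each block
  for (b in 1:4) {
    bt <- man$trials$ball_type[man$trials$block == b]
    expect_lte(abs(mean(bt == "normal") - 0.67), 1 / length(bt) + 1e-9)
  }
})

test_that("a full 72-trial session has 288 trials and 24 probe rows", {
  s <- simulate_session(seed = 4, participants = 1, keep_series = FALSE)
  expect_equal(nrow(s$trials), 288L)
  expect_equal(nrow(s$probes), 24L)
  expect_true(all(s$probes$pof >= 0 & s$probes$pof <= 6))
  expect_true(all(s$probes$cof >= 0 & s$probes$cof <= 6))
  expect_true(all(s$probes$anxiety >= 0 & s$probes$anxiety <= 10))
})
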