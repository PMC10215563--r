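# Whole-session simulation: four 72-trial blocks (2x2 pressure by failure
# feedback, counterbalanced order), per-trial time series in the trial file
# schema, a manifest with the bogus-feedback schedule and true interception
# ground truth, and probe self-reports.

#' Session-level simulator configuration
#'
#' @param n_trials Trials per block.
#' @param true_hit_rate Mean probability a trial is truly intercepted
#'   (independent of the bogus feedback calls).
#' @param hit_rate_sd Between-participant SD of interception skill on the
#'   logit scale (0 = identical skill).
#' @param pre_roll_s Stationary ball hold before release, s.
#' @param tail_s Recording tail after contact, s.
#' @return A list of class \code{"ivr_session_config"}.
#' @export
session_config <- function(n_trials = 72L, true_hit_rate = 0.75,
                           hit_rate_sd = 0.5,
                           pre_roll_s = 0.2, tail_s = 0.3) {
  if (true_hit_rate < 0 || true_hit_rate > 1)
    stop("session config: `true_hit_rate` must be in [0, 1]", call. = FALSE)
  if (hit_rate_sd < 0)
    stop("session config: `hit_rate_sd` must be >= 0", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials),
                 true_hit_rate = true_hit_rate,
                 hit_rate_sd = hit_rate_sd,
                 pre_roll_s = pre_roll_s, tail_s = tail_s),
            class = "ivr_session_config")
}

#' Simulate one trial (time series plus ground truth)
#'
#' @param ball_type "normal" or "elastic".
#' @param hit Logical: is the ball truly intercepted?
#' @param physics,gaze,swing Configuration objects.
#' @param session A \code{\link{session_config}}.
#' @param seed Integer seed (gaze jitter/dropout and swing noise).
#' @return List of class \code{"ivr_trial"}: \code{raw} (trial-schema
#'   data.frame) and \code{truth} (landmarks, gaze events, swing truth, hit).
#' @export
simulate_trial <- function(ball_type = "normal", hit = TRUE,
                           physics = physics_config(),
                           gaze = gaze_config(),
                           swing = swing_config(),
                           session = session_config(),
                           seed = NULL) {
  ball <- ball_trajectory(ball_type, physics,
                          outcome = if (hit) "hit" else "miss",
                          pre_roll_s = session$pre_roll_s,
                          tail_s = session$tail_s)
  head <- head_pose(physics)
  gz <- generate_gaze(ball, gaze, head,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
  sw <- generate_swing(ball, swing, hit = hit, head = head,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, 2L))
  n <- nrow(ball$series)
  raw <- data.frame(
    time_s = ball$series$time_s,
    head_x = head$position[1], head_y = head$position[2], head_z = head$position[3],
    head_qw = head$quat[1], head_qx = head$quat[2],
    head_qy = head$quat[3], head_qz = head$quat[4],
    ctrl_x = sw$pos[, 1], ctrl_y = sw$pos[, 2], ctrl_z = sw$pos[, 3],
    ctrl_qw = sw$quat[, 1], ctrl_qx = sw$quat[, 2],
    ctrl_qy = sw$quat[, 3], ctrl_qz = sw$quat[, 4],
    gaze_origin_x = head$position[1], gaze_origin_y = head$position[2],
    gaze_origin_z = head$position[3],
    gaze_dir_x = gz$dir[, 1], gaze_dir_y = gz$dir[, 2], gaze_dir_z = gz$dir[, 3],
    ball_x = ball$series$x, ball_y = ball$series$y, ball_z = ball$series$z,
    gaze_valid = as.integer(gz$valid))
  truth <- list(ball_type = ball_type, hit = hit,
                release_frame = ball$release_frame,
                bounce_frame = ball$bounce_frame,
                contact_frame = ball$contact_frame,
                post_bounce_vertical_speed = ball$post_bounce_vertical_speed,
                gaze_events = gz$events,
                bounce_fixation_pitch = gz$bounce_fixation_pitch,
                peak_swing_speed = sw$peak_speed,
                foreswing_onset = sw$foreswing_onset)
  structure(list(raw = raw, truth = truth), class = "ivr_trial")
}

#' Simulate a full session for one or more participants
#'
#' Each participant completes four blocks (the 2x2 pressure by failure
#' feedback cells) of \code{n_trials} trials in a seeded counterbalanced
#' order, with per-block bogus feedback schedules, ball-type sequences, six
#' probes per block and probe self-reports. Identical seeds yield identical
#' sessions (and byte-identical files when written).
#'
#' @param config List as returned by \code{\link{load_config}} (defaults
#'   used where \code{NULL}).
#' @param seed Integer seed.
#' @param participants Number of participants, or a character vector of ids.
#' @param out_dir Optional directory; when given, trial CSVs and the manifest
#'   are written there (one subdirectory per participant).
#' @param keep_series Keep the simulated time series in the returned object?
#'   (Set \code{FALSE} with \code{out_dir} to bound memory.)
#' @return List of class \code{"ivr_session"}: \code{trials} (manifest
#'   table), \code{probes} (probe table with self-reports), and
#'   \code{recordings} (named list of \code{ivr_trial}, if kept).
#' @export
simulate_session <- function(config = load_config(), seed = 1L,
                             participants = 1L, out_dir = NULL,
                             keep_series = is.null(out_dir)) {
  if (is.numeric(participants))
    participants <- sprintf("P%02d", seq_len(participants))
  ses <- config$session %||% session_config()
  phys <- config$physics %||% physics_config()
  gcfg <- config$gaze %||% gaze_config()
  scfg <- config$swing %||% swing_config()
  truth <- config$selfreport %||% selfreport_truth()

  cells <- expand.grid(pressure = c("low", "high"),
                       feedback = c("low", "high"),
                       stringsAsFactors = FALSE)
  trials_out <- list()
  probes_out <- list()
  recordings <- list()

  for (i in seq_along(participants)) {
    pid <- participants[i]
    set.seed(derive_seed(seed, 100000L + i))
    block_order <- sample(4L)
    # participant skill: random intercept on the logit of the hit rate
    p_hit_i <- stats::plogis(stats::qlogis(ses$true_hit_rate) +
                               stats::rnorm(1L, 0, ses$hit_rate_sd))
    pdir <- if (!is.null(out_dir)) file.path(out_dir, pid) else NULL
    if (!is.null(pdir) && !dir.exists(pdir)) dir.create(pdir, recursive = TRUE)
    for (b_pos in seq_len(4L)) {
      cell <- block_order[b_pos]
      sch <- build_feedback_schedule(cells$feedback[cell],
                                     n_trials = ses$n_trials,
                                     seed = derive_seed(seed, i * 1000L + cell))
      set.seed(derive_seed(seed, i * 1000L + 500L + cell))
      hits <- stats::runif(ses$n_trials) < p_hit_i
      for (t in seq_len(ses$n_trials)) {
        trial_seed <- derive_seed(seed, i * 100000L + cell * 1000L + t)
        rec <- simulate_trial(sch$ball_types[t], hit = hits[t],
                              physics = phys, gaze = gcfg, swing = scfg,
                              session = ses, seed = trial_seed)
        fname <- sprintf("%s_b%d_t%03d.csv", pid, b_pos, t)
        if (!is.null(pdir)) write_trial_csv(rec$raw, file.path(pdir, fname))
        if (keep_series) recordings[[paste(pid, b_pos, t, sep = "_")]] <- rec
        trials_out[[length(trials_out) + 1L]] <- data.frame(
          participant = pid, block = b_pos,
          pressure = cells$pressure[cell], feedback = cells$feedback[cell],
          trial = t, ball_type = sch$ball_types[t],
          feedback_call = sch$feedback_calls[t],
          probe = as.integer(t %in% sch$probe_trials),
          hit_truth = as.integer(hits[t]),
          file = fname, stringsAsFactors = FALSE)
      }
      probes_out[[length(probes_out) + 1L]] <- data.frame(
        participant = pid, block = b_pos,
        pressure = cells$pressure[cell], feedback = cells$feedback[cell],
        trial = sch$probe_trials,
        feedback_call = sch$feedback_calls[sch$probe_trials],
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, trials_out)
  probes <- do.call(rbind, probes_out)
  probes <- generate_selfreports(probes, truth, seed = derive_seed(seed, 999L))
  out <- structure(list(trials = trials, probes = probes,
                        recordings = if (keep_series) recordings else NULL,
                        seed = seed),
                   class = "ivr_session")
  if (!is.null(out_dir))
    write_manifest(list(trials = trials, probes = probes), out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
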