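# Synthetic gaze for one interception trial. The generated sequence mirrors
# the predictive strategy seen in interceptive sports: pursuit of the early
# ball flight, one anticipatory saccade to a point a few degrees above the
# predicted bounce location, a bounce fixation held through the bounce, then
# a catch-up saccade and pursuit of the ball onto the racquet. Every injected
# event is returned with its exact frames, so detectors can be scored against
# ground truth.

#' Gaze generator configuration
#'
#' Event magnitudes are generator choices (the recorded task constrains only
#' the structure of the sequence); defaults are plausible for a ~2.5 s trial
#' viewed from 3-9 m.
#'
#' @param pursuit_gain Fraction of the ball's angular displacement matched
#'   during pursuit (0 to 1.2).
#' @param saccade_peak_velocity Nominal saccade peak velocity, deg/s; actual
#'   peak is \code{2 * amplitude / duration} after the duration is clamped to
#'   \code{min_saccade_s}.
#' @param bounce_fixation_pitch_offset Fixation pitch above the bounce-point
#'   direction, deg.
#' @param bounce_fixation_lead Fixation onset before the bounce, s.
#' @param post_bounce_fixation_s Fixation hold after the bounce, s.
#' @param fixation_jitter_sd Per-frame angular jitter during fixations, deg.
#' @param dropout_rate Per-frame probability that a missing-sample run starts.
#' @param dropout_run_length Length of each missing-sample run, frames.
#' @param min_saccade_s Minimum saccade duration, s.
#' @param catchup Insert a catch-up saccade after the bounce fixation?
#' @return A validated list of class \code{"ivr_gaze_config"}.
#' @export
gaze_config <- function(pursuit_gain = 0.9,
                        saccade_peak_velocity = 350,
                        bounce_fixation_pitch_offset = 8,
                        bounce_fixation_lead = 0.2,
                        post_bounce_fixation_s = 0.3,
                        fixation_jitter_sd = 0.1,
                        dropout_rate = 0.005,
                        dropout_run_length = 3L,
                        min_saccade_s = 0.1,
                        catchup = TRUE) {
  if (pursuit_gain < 0 || pursuit_gain > 1.2)
    stop("gaze config: `pursuit_gain` must be in [0, 1.2]", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("gaze config: `dropout_rate` must be in [0, 1]", call. = FALSE)
  if (saccade_peak_velocity <= 0)
    stop("gaze config: `saccade_peak_velocity` must be > 0", call. = FALSE)
  if (fixation_jitter_sd < 0)
    stop("gaze config: `fixation_jitter_sd` must be >= 0", call. = FALSE)
  structure(list(pursuit_gain = pursuit_gain,
                 saccade_peak_velocity = saccade_peak_velocity,
                 bounce_fixation_pitch_offset = bounce_fixation_pitch_offset,
                 bounce_fixation_lead = bounce_fixation_lead,
                 post_bounce_fixation_s = post_bounce_fixation_s,
                 fixation_jitter_sd = fixation_jitter_sd,
                 dropout_rate = dropout_rate,
                 dropout_run_length = as.integer(dropout_run_length),
                 min_saccade_s = min_saccade_s,
                 catchup = isTRUE(catchup)),
            class = "ivr_gaze_config")
}

#' Head pose for a generated trial
#'
#' The head is placed at the player's start position at eye height, oriented
#' toward the bounce point (players orient toward the interception zone), and
#' held fixed over the trial. With this pose the egocentric pitch of the
#' bounce fixation equals the configured pitch offset exactly.
#'
#' @param cfg A \code{\link{physics_config}}.
#' @return List with \code{position} (length-3) and \code{quat} (w, x, y, z).
#' @export
head_pose <- function(cfg = physics_config()) {
  pos <- c(-cfg$lateral_start_offset, cfg$eye_height, 0)
  bounce <- c(0, 0, cfg$bounce_distance_ahead)
  ang <- dir_to_angles(bounce - pos)
  R <- look_rotation(ang$yaw, ang$pitch)
  list(position = pos, quat = mat_to_quat(R))
}

# displacement fraction of a triangular velocity profile at phase u in [0,1]
tri_displacement <- function(u) ifelse(u <= 0.5, 2 * u^2, 1 - 2 * (1 - u)^2)

#' Generate a synthetic gaze track with ground-truth events
#'
#' @param ball An \code{\link{ball_trajectory}} result.
#' @param cfg A \code{\link{gaze_config}}.
#' @param head A \code{\link{head_pose}} (must share the ball's time base).
#' @param seed Optional integer seed for jitter and dropout.
#' @return A list of class \code{"ivr_gaze"}: \code{dir} (n x 3 world-frame
#'   unit gaze vectors), \code{valid} (logical; FALSE inside dropout runs),
#'   \code{events} (data.frame: class, role, onset, offset (exclusive),
#'   amplitude_deg, peak_velocity), and \code{head}.
#' @export
generate_gaze <- function(ball, cfg = gaze_config(), head = head_pose(ball$cfg),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  series <- ball$series
  n <- nrow(series)
  dt <- series$time_s[2L] - series$time_s[1L]
  eye <- head$position
  rel <- cbind(series$x - eye[1], series$y - eye[2], series$z - eye[3])
  ball_ang <- dir_to_angles(rel)

  bounce_dir <- c(0, 0, ball$cfg$bounce_distance_ahead) - eye
  bounce_ang <- dir_to_angles(bounce_dir)
  fix_ang <- c(bounce_ang$yaw, bounce_ang$pitch + cfg$bounce_fixation_pitch_offset)

  r <- ball$release_frame
  b <- ball$bounce_frame
  min_m <- max(3L, ceiling(cfg$min_saccade_s / dt))
  lead <- round(cfg$bounce_fixation_lead / dt)
  post <- round(cfg$post_bounce_fixation_s / dt)

  yaw <- numeric(n); pitch <- numeric(n)
  events <- list()
  add_event <- function(class, role, onset, offset, amp = NA_real_, pk = NA_real_) {
    events[[length(events) + 1L]] <<- data.frame(
      class = class, role = role, onset = onset, offset = offset,
      amplitude_deg = amp, peak_velocity = pk)
  }

  # launch hold: fixation on the ball's launch port
  yaw[1:(r - 1L)] <- ball_ang$yaw[1L]
  pitch[1:(r - 1L)] <- ball_ang$pitch[1L]
  add_event("fixation", "launch_hold", 1L, r)

  # saccade duration from configured peak velocity and the amplitude at onset
  # (estimated from the pursuit position just before the jump)
  fix_on <- b - lead                       # first fixation frame
  approx_amp <- great_circle_deg(
    angles_to_dir(ball_ang$yaw[fix_on], ball_ang$pitch[fix_on]),
    angles_to_dir(fix_ang[1], fix_ang[2]))
  m1 <- max(min_m, ceiling(2 * approx_amp / cfg$saccade_peak_velocity / dt))
  s1_on <- fix_on - m1
  if (s1_on <= r + 2L)
    stop("trial too short for the configured saccade/fixation timing",
         call. = FALSE)

  # early pursuit of the ball
  idx <- r:(s1_on - 1L)
  yaw[idx] <- yaw[r - 1L] + cfg$pursuit_gain * (ball_ang$yaw[idx] - ball_ang$yaw[r - 1L])
  pitch[idx] <- pitch[r - 1L] + cfg$pursuit_gain * (ball_ang$pitch[idx] - ball_ang$pitch[r - 1L])
  add_event("pursuit", "pre_bounce_pursuit", r, s1_on)

  # predictive saccade: spherical interpolation, triangular velocity profile
  from <- angles_to_dir(yaw[s1_on - 1L], pitch[s1_on - 1L])[1L, ]
  to <- angles_to_dir(fix_ang[1], fix_ang[2])[1L, ]
  amp1 <- great_circle_deg(from, to)
  u <- tri_displacement(seq_len(m1) / m1)
  sd1 <- slerp(from, to, u)
  sac_ang <- dir_to_angles(sd1)
  yaw[s1_on:(fix_on - 1L)] <- sac_ang$yaw
  pitch[s1_on:(fix_on - 1L)] <- sac_ang$pitch
  add_event("saccade", "predictive_saccade", s1_on, fix_on,
            amp = amp1, pk = 2 * amp1 / (m1 * dt))

  # bounce fixation held through the bounce
  fix_off <- b + post
  yaw[fix_on:(fix_off - 1L)] <- fix_ang[1]
  pitch[fix_on:(fix_off - 1L)] <- fix_ang[2]
  add_event("fixation", "bounce_fixation", fix_on, fix_off)

  cursor <- fix_off
  if (cfg$catchup && fix_off + min_m < n) {
    m2 <- min_m
    c_off <- fix_off + m2
    from2 <- angles_to_dir(fix_ang[1], fix_ang[2])[1L, ]
    to2 <- angles_to_dir(ball_ang$yaw[c_off - 1L], ball_ang$pitch[c_off - 1L])[1L, ]
    amp2 <- great_circle_deg(from2, to2)
    m2 <- max(min_m, ceiling(2 * amp2 / cfg$saccade_peak_velocity / dt))
    c_off <- fix_off + m2
    to2 <- angles_to_dir(ball_ang$yaw[c_off - 1L], ball_ang$pitch[c_off - 1L])[1L, ]
    amp2 <- great_circle_deg(from2, to2)
    u2 <- tri_displacement(seq_len(m2) / m2)
    sd2 <- slerp(from2, to2, u2)
    ca <- dir_to_angles(sd2)
    yaw[fix_off:(c_off - 1L)] <- ca$yaw
    pitch[fix_off:(c_off - 1L)] <- ca$pitch
    add_event("saccade", "catchup_saccade", fix_off, c_off,
              amp = amp2, pk = 2 * amp2 / (m2 * dt))
    cursor <- c_off
  }

  # post-bounce pursuit to the end of the recording
  if (cursor <= n) {
    idx <- cursor:n
    yaw[idx] <- yaw[cursor - 1L] + cfg$pursuit_gain * (ball_ang$yaw[idx] - ball_ang$yaw[cursor - 1L])
    pitch[idx] <- pitch[cursor - 1L] + cfg$pursuit_gain * (ball_ang$pitch[idx] - ball_ang$pitch[cursor - 1L])
    add_event("pursuit", "post_bounce_pursuit", cursor, n + 1L)
  }

  # fixation jitter
  if (cfg$fixation_jitter_sd > 0) {
    ev <- do.call(rbind, events)
    for (k in which(ev$class == "fixation")) {
      idx <- ev$onset[k]:(ev$offset[k] - 1L)
      yaw[idx] <- yaw[idx] + stats::rnorm(length(idx), 0, cfg$fixation_jitter_sd)
      pitch[idx] <- pitch[idx] + stats::rnorm(length(idx), 0, cfg$fixation_jitter_sd)
    }
  }

  dir <- angles_to_dir(yaw, pitch)

  # missing-sample runs
  valid <- rep(TRUE, n)
  if (cfg$dropout_rate > 0) {
    starts <- which(stats::runif(n) < cfg$dropout_rate)
    for (s in starts) valid[s:min(n, s + cfg$dropout_run_length - 1L)] <- FALSE
    dir[!valid, ] <- 0
  }

  structure(list(dir = dir, valid = valid,
                 events = do.call(rbind, events),
                 head = head,
                 bounce_fixation_pitch = cfg$bounce_fixation_pitch_offset),
            class = "ivr_gaze")
}
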