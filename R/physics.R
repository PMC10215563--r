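# Ball flight for the virtual racquetball task: a ballistic launch from the
# front wall, a single restitution bounce on the floor, and either a racquet
# contact (abrupt velocity change) or an unimpeded pass beyond the player.

#' Physics configuration for the virtual court and ball
#'
#' Defaults describe the task environment: a 15 m court, launch from a 2 m
#' high port on the front wall, the player's start position 9 m behind the
#' wall and 0.75 m left of the midline, a bounce 3.5 m in front of the start
#' position reached with a vertical speed of -9 m/s under -9.8 m/s^2 gravity,
#' and two ball elasticities (0.65 "normal", 0.85 "elastic"). The visible
#' racquet is 0.6 x 0.3 x 0.01 m; its collision thickness is exaggerated by
#' 0.20 m for hit detection.
#'
#' @param gravity Vertical acceleration, m/s^2 (negative = downward).
#' @param bounce_vertical_speed Vertical velocity at the moment of floor
#'   contact, m/s (negative = downward).
#' @param elasticity_normal,elasticity_elastic Restitution fractions in (0,1).
#' @param ball_diameter Ball diameter, m.
#' @param bounce_distance_ahead Bounce point distance in front of the start
#'   position, m.
#' @param start_behind_wall Player start distance behind the front wall, m.
#' @param lateral_start_offset Player start offset left of the midline, m.
#' @param launch_height Launch port height, m.
#' @param court_length Court length, m.
#' @param racquet_extent Visible racquet width/height/thickness, m.
#' @param collision_thickness Effective racquet thickness used for collision
#'   detection, m.
#' @param sample_rate Recording rate, Hz.
#' @param contact_depth Depth (z, m from the player) at which a well-timed
#'   swing meets the ball.
#' @param eye_height Eye height of the standing player, m.
#' @return A validated list of class \code{"ivr_physics_config"}.
#' @export
physics_config <- function(gravity = -9.8,
                           bounce_vertical_speed = -9,
                           elasticity_normal = 0.65,
                           elasticity_elastic = 0.85,
                           ball_diameter = 0.057,
                           bounce_distance_ahead = 3.5,
                           start_behind_wall = 9,
                           lateral_start_offset = 0.75,
                           launch_height = 2.0,
                           court_length = 15,
                           racquet_extent = c(0.6, 0.3, 0.01),
                           collision_thickness = 0.01 + 0.20,
                           sample_rate = 90,
                           contact_depth = 0.6,
                           eye_height = 1.7) {
  cfg <- list(gravity = gravity,
              bounce_vertical_speed = bounce_vertical_speed,
              elasticity_normal = elasticity_normal,
              elasticity_elastic = elasticity_elastic,
              ball_diameter = ball_diameter,
              bounce_distance_ahead = bounce_distance_ahead,
              start_behind_wall = start_behind_wall,
              lateral_start_offset = lateral_start_offset,
              launch_height = launch_height,
              court_length = court_length,
              racquet_extent = racquet_extent,
              collision_thickness = collision_thickness,
              sample_rate = sample_rate,
              contact_depth = contact_depth,
              eye_height = eye_height)
  class(cfg) <- "ivr_physics_config"
  validate_physics_config(cfg)
}

validate_physics_config <- function(cfg) {
  chk <- function(ok, key, bound) {
    if (!ok) stop(sprintf("physics config: `%s` must be %s", key, bound),
                  call. = FALSE)
  }
  chk(cfg$elasticity_normal > 0 && cfg$elasticity_normal < 1,
      "elasticity_normal", "in (0, 1)")
  chk(cfg$elasticity_elastic > 0 && cfg$elasticity_elastic < 1,
      "elasticity_elastic", "in (0, 1)")
  chk(cfg$sample_rate > 0, "sample_rate", "> 0")
  chk(cfg$bounce_distance_ahead < cfg$start_behind_wall,
      "bounce_distance_ahead", "< start_behind_wall")
  chk(cfg$gravity < 0, "gravity", "< 0 (downward)")
  chk(cfg$bounce_vertical_speed < 0, "bounce_vertical_speed",
      "< 0 (downward at floor contact)")
  chk(cfg$launch_height > 0, "launch_height", "> 0")
  chk(length(cfg$racquet_extent) == 3L && all(cfg$racquet_extent > 0),
      "racquet_extent", "a positive length-3 extent")
  cfg
}

# Launch solution: vertical launch speed and flight time so that the floor is
# reached with the configured downward speed from the configured height, and
# horizontal depth speed so the bounce lands at the configured point.
launch_solution <- function(cfg) {
  g <- cfg$gravity
  vb <- cfg$bounce_vertical_speed
  v0y <- sqrt(vb^2 + 2 * g * cfg$launch_height)
  t_b <- (vb - v0y) / g
  vz <- -(cfg$start_behind_wall - cfg$bounce_distance_ahead) / t_b
  list(v0y = v0y, flight_time = t_b, vz = vz)
}

#' Generate a sampled ball trajectory
#'
#' Produces the piecewise-ballistic ball path of one trial at the recording
#' rate: a stationary pre-release hold at the launch port, a pre-bounce
#' ballistic segment (identical for both ball types), an instantaneous bounce
#' that reverses the vertical velocity scaled by the ball's elasticity while
#' conserving horizontal velocity, and then either a racquet contact
#' (\code{outcome = "hit"}: an abrupt velocity change at the contact frame,
#' as the ball is struck back up-court) or a continuation past the player
#' (\code{outcome = "miss"}).
#'
#' @param ball_type \code{"normal"} or \code{"elastic"}.
#' @param cfg A \code{\link{physics_config}}.
#' @param outcome \code{"hit"} or \code{"miss"}.
#' @param pre_roll_s Stationary hold before release, s.
#' @param tail_s Extra recording after contact (hit trials), s.
#' @param miss_end_z Depth (m) at which a missed trial's recording ends.
#' @return A list of class \code{"ivr_ball"}: \code{series} (data.frame with
#'   \code{time_s, x, y, z}), ground-truth landmark frames
#'   (\code{release_frame}, \code{bounce_frame}, \code{contact_frame} -- the
#'   racquet-contact frame for hits, the nominal contact-depth crossing for
#'   misses), \code{outcome}, and the launch solution.
#' @export
ball_trajectory <- function(ball_type = c("normal", "elastic"), cfg = physics_config(),
                            outcome = c("miss", "hit"),
                            pre_roll_s = 0.2, tail_s = 0.3, miss_end_z = -0.5) {
  ball_type <- match.arg(ball_type)
  outcome <- match.arg(outcome)
  cfg <- validate_physics_config(cfg)
  e <- if (ball_type == "normal") cfg$elasticity_normal else cfg$elasticity_elastic
  g <- cfg$gravity
  dt <- 1 / cfg$sample_rate
  sol <- launch_solution(cfg)
  launch <- c(0, cfg$launch_height, cfg$start_behind_wall)
  v0 <- c(0, sol$v0y, sol$vz)
  t_bounce <- sol$flight_time
  v1y <- e * abs(cfg$bounce_vertical_speed)
  bounce_pt <- c(0, 0, cfg$bounce_distance_ahead)

  pos_at <- function(tau) {
    # tau: time since release; vectorised closed-form piecewise path
    pre <- tau <= 0
    up <- tau > 0 & tau <= t_bounce
    dn <- tau > t_bounce
    x <- numeric(length(tau)); y <- x; z <- x
    x[pre] <- launch[1]; y[pre] <- launch[2]; z[pre] <- launch[3]
    tu <- tau[up]
    y[up] <- launch[2] + v0[2] * tu + 0.5 * g * tu^2
    z[up] <- launch[3] + v0[3] * tu
    td <- tau[dn] - t_bounce
    y[dn] <- v1y * td + 0.5 * g * td^2
    z[dn] <- bounce_pt[3] + v0[3] * td
    cbind(x = x, y = y, z = z)
  }

  # nominal contact-depth crossing time (since release)
  t_cross <- t_bounce + (cfg$bounce_distance_ahead - cfg$contact_depth) / (-v0[3])
  t_end_miss <- t_bounce + (cfg$bounce_distance_ahead - miss_end_z) / (-v0[3])

  release_time <- pre_roll_s
  # contact pinned to the sample grid so the kink sits on one frame
  k_contact <- as.integer(ceiling((release_time + t_cross) / dt)) + 1L
  t_contact <- (k_contact - 1L) * dt
  n <- if (outcome == "hit") k_contact + as.integer(ceiling(tail_s / dt))
       else as.integer(ceiling((release_time + t_end_miss) / dt)) + 1L
  t <- (seq_len(n) - 1L) * dt
  pos <- pos_at(t - release_time)
  if (outcome == "hit") {
    # struck back up-court: velocity changes abruptly at the contact frame
    p_c <- pos_at(t_contact - release_time)[1L, ]
    v_after <- c(0, 2.0, -v0[3])
    after <- t > t_contact
    ta <- t[after] - t_contact
    pos[after, 1] <- p_c[1]
    pos[after, 2] <- p_c[2] + v_after[2] * ta + 0.5 * g * ta^2
    pos[after, 3] <- p_c[3] + v_after[3] * ta
  }
  series <- data.frame(time_s = t, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  release_frame <- which(t - release_time > 0)[1L]
  # bounce landmark: sampled frame of minimum height between release and
  # contact/end (matches the detector's position-minimum rule)
  upto <- if (outcome == "hit") k_contact else n
  seg <- seq(release_frame, upto)
  bounce_frame <- seg[which.min(series$y[seg])]
  structure(list(series = series,
                 ball_type = ball_type,
                 outcome = outcome,
                 release_frame = release_frame,
                 bounce_frame = bounce_frame,
                 contact_frame = k_contact,
                 contact_time = t_contact,
                 post_bounce_vertical_speed = v1y,
                 launch = sol,
                 cfg = cfg),
            class = "ivr_ball")
}
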