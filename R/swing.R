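# Synthetic hand-controller (racquet) motion: rest, a backswing away from the
# ball, then a foreswing whose speed follows a sin^2 bell peaking mid-swing,
# ending at the aim point at the contact frame.

#' Swing generator configuration
#'
#' @param peak_speed Foreswing peak speed, m/s.
#' @param backswing_amp Backswing displacement away from the aim point, m.
#' @param backswing_s Backswing duration, s.
#' @param rest_offset Hand rest position relative to the head, m (x right,
#'   y up, z forward).
#' @param noise_sd Per-coordinate positional noise, m.
#' @param miss_offset Lateral aim error applied on missed trials, m.
#' @return A list of class \code{"ivr_swing_config"}.
#' @export
swing_config <- function(peak_speed = 4.0, backswing_amp = 0.25,
                         backswing_s = 0.3,
                         rest_offset = c(0.35, -0.7, 0.3),
                         noise_sd = 0, miss_offset = 0.5) {
  if (peak_speed < 0) stop("swing config: `peak_speed` must be >= 0", call. = FALSE)
  if (backswing_amp < 0) stop("swing config: `backswing_amp` must be >= 0", call. = FALSE)
  structure(list(peak_speed = peak_speed, backswing_amp = backswing_amp,
                 backswing_s = backswing_s, rest_offset = rest_offset,
                 noise_sd = noise_sd, miss_offset = miss_offset),
            class = "ivr_swing_config")
}

# displacement fraction for a sin^2 speed bell: s(u) = u - sin(2*pi*u)/(2*pi)
bell_displacement <- function(u) u - sin(2 * pi * u) / (2 * pi)

#' Generate a synthetic swing (controller pose series)
#'
#' The controller rests beside the player, performs a backswing away from the
#' aim point, then a foreswing with a sin^2 (bell-shaped) speed profile whose
#' configured peak occurs mid-swing, reaching the aim point exactly at the
#' contact frame. On missed trials the aim point is displaced laterally by
#' \code{miss_offset}. The foreswing duration is derived from the travel
#' distance and the configured peak speed so the bell integrates to the
#' required displacement.
#'
#' @param ball An \code{\link{ball_trajectory}} result.
#' @param cfg A \code{\link{swing_config}}.
#' @param hit Logical: should the swing meet the ball?
#' @param head A \code{\link{head_pose}} (rest position is head-relative).
#' @param seed Optional seed for positional noise.
#' @return A list of class \code{"ivr_swing"}: \code{pos} (n x 3), \code{quat}
#'   (n x 4, identity), \code{aim}, ground-truth \code{peak_speed},
#'   \code{foreswing_onset} and \code{contact_frame}.
#' @export
generate_swing <- function(ball, cfg = swing_config(), hit = TRUE,
                           head = head_pose(ball$cfg), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  series <- ball$series
  n <- nrow(series)
  dt <- series$time_s[2L] - series$time_s[1L]
  k_c <- ball$contact_frame
  aim <- as.numeric(series[k_c, c("x", "y", "z")])
  if (!hit) {
    # aim wide of the ball, resting on the nominal contact-depth plane so the
    # ball's depth passes the racquet exactly at the nominal contact frame
    aim[1] <- aim[1] + cfg$miss_offset
    aim[3] <- ball$cfg$contact_depth
  }
  rest <- head$position + cfg$rest_offset

  pos <- matrix(rep(rest, each = n), n, 3L)
  truth_peak <- 0
  fs_on <- NA_integer_
  if (cfg$peak_speed > 0) {
    d0 <- aim - rest
    d0 <- d0 / sqrt(sum(d0^2))
    back_start <- rest
    back_end <- rest - cfg$backswing_amp * d0
    travel <- sqrt(sum((aim - back_end)^2))
    fore_s <- 2 * travel / cfg$peak_speed
    m_fore <- max(6L, round(fore_s / dt))
    m_back <- max(4L, round(cfg$backswing_s / dt))
    fs_on <- k_c - m_fore
    bs_on <- fs_on - m_back
    if (bs_on < 2L)
      stop("trial too short for the configured swing timing", call. = FALSE)
    ub <- bell_displacement(seq_len(m_back) / m_back)
    pos[bs_on:(fs_on - 1L), ] <- rep(back_start, each = m_back) +
      outer(ub, back_end - back_start)
    # frame fs_on has u = 0 (coincides with the backswing end), frame k_c has
    # u = 1 (the aim point at contact)
    uf <- bell_displacement(0:m_fore / m_fore)
    pos[fs_on:k_c, ] <- rep(back_end, each = m_fore + 1L) +
      outer(uf, aim - back_end)
    if (k_c < n)
      pos[(k_c + 1L):n, ] <- rep(aim, each = n - k_c)
    # ground-truth peak of the sampled profile (grid discretization makes it
    # a hair under the nominal peak_speed)
    truth_peak <- travel * max(diff(uf)) / dt
  }
  if (cfg$noise_sd > 0)
    pos <- pos + matrix(stats::rnorm(3L * n, 0, cfg$noise_sd), n, 3L)
  quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4L)
  structure(list(pos = pos, quat = quat, aim = aim,
                 peak_speed = truth_peak, foreswing_onset = fs_on,
                 contact_frame = k_c, hit = hit),
            class = "ivr_swing")
}
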