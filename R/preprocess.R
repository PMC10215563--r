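# Trial preprocessing: segmentation from ball release to racquet contact,
# zero-phase Butterworth denoising (dual-pass 10 Hz for positional data; a
# three-frame median filter followed by a second-order zero-lag Butterworth
# at 50 Hz for saccade identification and 15 Hz for positional gaze
# features), gaze-in-world yaw/pitch and egocentric pitch, great-circle
# angular kinematics, missing-data exclusion rules and per-condition
# winsorization.

#' Preprocessing configuration
#'
#' @param positional_cutoff_hz Low-pass cutoff for head/controller position
#'   series (dual-pass Butterworth), Hz.
#' @param gaze_saccade_cutoff_hz Gaze cutoff used for saccade identification,
#'   Hz (clamped to 0.99 x Nyquist with a warning if too high).
#' @param gaze_position_cutoff_hz Gaze cutoff used for positional tracking
#'   features, Hz.
#' @param max_missing_frac Exclusion threshold on the fraction of missing
#'   gaze samples in the segmented window (strictly greater excludes).
#' @param max_gap_ms Exclusion threshold on the longest contiguous missing
#'   run (strictly greater excludes), ms.
#' @param winsor_k Winsorization boundary in within-group SD units.
#' @param butter_order Butterworth order per pass.
#' @return A list of class \code{"ivr_preprocess_config"}.
#' @export
preprocess_config <- function(positional_cutoff_hz = 10,
                              gaze_saccade_cutoff_hz = 50,
                              gaze_position_cutoff_hz = 15,
                              max_missing_frac = 0.20,
                              max_gap_ms = 100,
                              winsor_k = 3,
                              butter_order = 2L) {
  if (positional_cutoff_hz <= 0) stop("preprocess config: `positional_cutoff_hz` must be > 0", call. = FALSE)
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("preprocess config: `max_missing_frac` must be in [0, 1]", call. = FALSE)
  structure(list(positional_cutoff_hz = positional_cutoff_hz,
                 gaze_saccade_cutoff_hz = gaze_saccade_cutoff_hz,
                 gaze_position_cutoff_hz = gaze_position_cutoff_hz,
                 max_missing_frac = max_missing_frac,
                 max_gap_ms = max_gap_ms,
                 winsor_k = winsor_k,
                 butter_order = as.integer(butter_order)),
            class = "ivr_preprocess_config")
}

# zero-phase (forward-backward) Butterworth on one series, with odd
# reflection padding at both ends to absorb the filter transient; NA runs
# are preserved and each contiguous valid run is filtered independently.
zero_phase_butter <- function(x, cutoff, fs, order = 2L) {
  ny <- fs / 2
  if (cutoff >= ny) stop("filter cutoff must be below the Nyquist frequency (",
                         ny, " Hz)", call. = FALSE)
  # above ~0.95 x Nyquist a low-order Butterworth has unity gain to within
  # 1e-3 but a numerically treacherous recursion (poles hugging z = -1);
  # the sound realization of "hardly any filtering" is the identity
  if (cutoff / ny >= 0.95) return(x)
  bf <- signal::butter(order, cutoff / ny)
  pad <- 4L * (order + 1L)
  out <- x
  for (run in na_runs(!is.na(x))) {
    seg <- x[run]
    n <- length(seg)
    if (n <= pad + 1L) next   # too short for the filter warm-up: left as-is
    p <- min(pad, n - 1L)
    # demeaning makes constants exact (zeros filter to zeros) and shrinks the
    # residual edge transient to the scale of the fluctuations
    mu <- mean(seg)
    seg <- seg - mu
    ext <- c(2 * seg[1L] - seg[(p + 1L):2L], seg, 2 * seg[n] - seg[(n - 1L):(n - p)])
    y <- signal::filter(bf, ext)
    y <- rev(signal::filter(bf, rev(y)))
    out[run] <- y[(p + 1L):(p + n)] + mu
  }
  out
}

# index runs where `ok` is TRUE, as a list of integer vectors
na_runs <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(k) starts[k]:ends[k])
}

#' Low-pass filter positional data (dual-pass, zero-phase Butterworth)
#'
#' @param series Numeric vector, or a data.frame/matrix filtered columnwise.
#' @param cutoff Cutoff frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param order Butterworth order per pass.
#' @return Filtered series of the same shape.
#' @export
filter_positional <- function(series, cutoff = 10, fs = 90, order = 2L) {
  if (is.null(dim(series)))
    return(zero_phase_butter(series, cutoff, fs, order))
  out <- series
  for (j in seq_len(ncol(series)))
    out[, j] <- zero_phase_butter(series[, j], cutoff, fs, order)
  out
}

# three-frame median filter (endpoints copied); NAs propagate locally
median3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  a <- x[1:(n - 2L)]; b <- x[2:(n - 1L)]; c <- x[3:n]
  mid <- pmax(pmin(a, b), pmin(pmax(a, b), c))
  c(x[1L], mid, x[n])
}

#' Filter gaze signals for a given analysis purpose
#'
#' A three-frame median filter followed by a second-order zero-lag
#' Butterworth low-pass: 50 Hz for \code{purpose = "saccade"}, 15 Hz for
#' \code{purpose = "position"}. A cutoff at or above the Nyquist frequency is
#' clamped to 0.99 x Nyquist with a warning.
#'
#' @param series Numeric vector, or data.frame/matrix filtered columnwise.
#' @param purpose \code{"saccade"} or \code{"position"}.
#' @param fs Sampling rate, Hz.
#' @param cfg A \code{\link{preprocess_config}}.
#' @return Filtered series of the same shape.
#' @export
filter_gaze <- function(series, purpose = c("saccade", "position"), fs = 90,
                        cfg = preprocess_config()) {
  purpose <- match.arg(purpose)
  cutoff <- if (purpose == "saccade") cfg$gaze_saccade_cutoff_hz else cfg$gaze_position_cutoff_hz
  ny <- fs / 2
  if (cutoff >= ny) {
    cutoff <- 0.99 * ny
    warning(sprintf("gaze filter cutoff clamped to %.2f Hz (0.99 x Nyquist)",
                    cutoff))
  }
  apply1 <- function(x) zero_phase_butter(median3(x), cutoff, fs, cfg$butter_order)
  if (is.null(dim(series))) return(apply1(series))
  out <- series
  for (j in seq_len(ncol(series))) out[, j] <- apply1(series[, j])
  out
}

#' Gaze direction to world and egocentric angles
#'
#' World yaw is rotation about the gravity-aligned vertical axis; world pitch
#' is the angular deviation from the horizontal plane at eye height.
#' Egocentric angles are the same quantities for the gaze vector expressed in
#' the head frame (head orientation quaternions, w-x-y-z).
#'
#' @param gaze_dir n x 3 matrix of gaze direction vectors (world frame).
#' @param head_quat n x 4 matrix (or length-4 vector) of head orientations.
#' @return data.frame with \code{yaw}, \code{pitch}, \code{ego_yaw},
#'   \code{ego_pitch} in degrees; zero-norm or NA vectors give NA rows.
#' @export
to_world_angles <- function(gaze_dir, head_quat) {
  if (is.null(dim(gaze_dir))) gaze_dir <- matrix(gaze_dir, ncol = 3L)
  n <- nrow(gaze_dir)
  if (is.null(dim(head_quat)))
    head_quat <- matrix(head_quat, n, 4L, byrow = TRUE)
  norms <- sqrt(rowSums(gaze_dir^2))
  bad <- is.na(norms) | norms < 1e-9
  world <- dir_to_angles(gaze_dir)
  ego_yaw <- rep(NA_real_, n); ego_pitch <- rep(NA_real_, n)
  # head orientation is piecewise constant in practice; cache rotations
  qkey <- apply(round(head_quat, 12L), 1L, paste, collapse = ",")
  for (key in unique(qkey[!bad])) {
    idx <- which(qkey == key & !bad)
    R <- quat_to_mat(head_quat[idx[1L], ])
    vh <- gaze_dir[idx, , drop = FALSE] %*% R   # R^T v, rowwise
    a <- dir_to_angles(vh)
    ego_yaw[idx] <- a$yaw
    ego_pitch[idx] <- a$pitch
  }
  world$yaw[bad] <- NA_real_
  world$pitch[bad] <- NA_real_
  data.frame(yaw = world$yaw, pitch = world$pitch,
             ego_yaw = ego_yaw, ego_pitch = ego_pitch)
}

#' Angular velocity and acceleration of a direction series
#'
#' Velocity is the great-circle angular distance between consecutive
#' direction vectors divided by the sample interval; acceleration is its
#' first difference divided by the interval. Missing samples propagate.
#'
#' @param dirs n x 3 matrix of direction vectors.
#' @param dt Sample interval, s.
#' @return data.frame with \code{velocity} (deg/s) and \code{acceleration}
#'   (deg/s^2); the first element(s) are NA.
#' @export
angular_kinematics <- function(dirs, dt) {
  n <- nrow(dirs)
  u <- unit_rows(dirs)
  vel <- c(NA_real_, great_circle_deg(u[-n, , drop = FALSE],
                                      u[-1L, , drop = FALSE]) / dt)
  acc <- c(NA_real_, diff(vel) / dt)
  data.frame(velocity = vel, acceleration = acc)
}

#' Segment a trial from ball release to racquet contact
#'
#' Release is the first frame of ball motion; the bounce is the frame of
#' minimum ball height after release; contact is the first post-bounce frame
#' whose discrete acceleration deviates from the ballistic (gravity-only)
#' prediction by more than 5 x its pre-bounce RMS residual, or -- for missed
#' trials -- the first frame where the ball's depth is beyond the racquet's.
#'
#' @param raw Trial data.frame in the trial schema.
#' @param fs Sampling rate, Hz.
#' @param gravity Vertical acceleration, m/s^2.
#' @return List: \code{release_frame}, \code{bounce_frame},
#'   \code{contact_frame}, \code{contact_kind} ("strike", "pass" or NA),
#'   \code{qc_flags} (character vector; "no_release" when the ball never
#'   moves, "no_contact" when no contact event is found).
#' @export
segment_trial <- function(raw, fs = 90, gravity = -9.8) {
  ball <- as.matrix(raw[, c("ball_x", "ball_y", "ball_z")])
  n <- nrow(ball)
  dt <- 1 / fs
  flags <- character()
  step <- sqrt(rowSums((ball[-1L, , drop = FALSE] - ball[-n, , drop = FALSE])^2))
  moving <- which(step > 1e-9)
  if (!length(moving)) {
    return(list(release_frame = NA_integer_, bounce_frame = NA_integer_,
                contact_frame = NA_integer_, contact_kind = NA_character_,
                qc_flags = "no_release"))
  }
  release <- moving[1L] + 1L
  bounce <- release - 1L + which.min(ball[release:n, 2L])
  # discrete-acceleration residual from the ballistic prediction
  acc <- (ball[3:n, , drop = FALSE] - 2 * ball[2:(n - 1L), , drop = FALSE] +
            ball[1:(n - 2L), , drop = FALSE]) / dt^2
  resid <- sqrt((acc[, 1L])^2 + (acc[, 2L] - gravity)^2 + (acc[, 3L])^2)
  resid <- c(NA_real_, resid, NA_real_)  # align to frames
  pre <- resid[seq(release + 2L, max(release + 2L, bounce - 2L))]
  base <- sqrt(mean(pre^2, na.rm = TRUE))
  thr <- max(5 * base, 1e-3)
  search <- seq(min(bounce + 2L, n), n - 1L)
  hit_i <- search[which(resid[search] > thr)[1L]]
  if (!is.na(hit_i)) {
    contact <- hit_i
    kind <- "strike"
  } else {
    beyond <- which(ball[, 3L] < raw$ctrl_z & seq_len(n) > bounce)
    if (length(beyond)) {
      contact <- beyond[1L]
      kind <- "pass"
    } else {
      contact <- NA_integer_
      kind <- NA_character_
      flags <- c(flags, "no_contact")
    }
  }
  list(release_frame = release, bounce_frame = bounce, contact_frame = contact,
       contact_kind = kind, qc_flags = flags)
}

#' Missing-data exclusion rule
#'
#' A trial's gaze analyses are excluded when more than
#' \code{max_missing_frac} of the segmented window is missing, or when any
#' contiguous missing run is longer than \code{max_gap_ms} (both strictly
#' greater; at 90 Hz a 9-frame gap is exactly 100 ms and is retained).
#'
#' @param missing Logical vector: TRUE where the gaze sample is missing
#'   (already restricted to the segmented window).
#' @param fs Sampling rate, Hz.
#' @param cfg A \code{\link{preprocess_config}}.
#' @return List: \code{excluded} (logical), \code{reason} (character or NA),
#'   \code{missing_frac}, \code{max_gap_ms}.
#' @export
exclude_trial <- function(missing, fs = 90, cfg = preprocess_config()) {
  frac <- mean(missing)
  r <- rle(missing)
  gap_frames <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  gap_ms <- gap_frames * 1000 / fs
  excluded <- frac > cfg$max_missing_frac || gap_ms > cfg$max_gap_ms
  reason <- if (!excluded) NA_character_
    else if (frac > cfg$max_missing_frac) "missing_fraction" else "tracking_gap"
  list(excluded = excluded, reason = reason,
       missing_frac = frac, max_gap_ms = gap_ms)
}

#' Winsorize values within condition groups
#'
#' Within each group, values strictly beyond mean +/- k*SD are replaced by
#' that boundary; the mean and SD are computed once on the original values.
#' Zero-variance groups (and groups smaller than 2) are returned unchanged.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (condition labels), same length.
#' @param k Boundary in SD units.
#' @return Winsorized numeric vector.
#' @export
winsorize <- function(values, group = rep(1L, length(values)), k = 3) {
  out <- values
  for (g in unique(group)) {
    idx <- which(group == g)
    v <- values[idx]
    keep <- !is.na(v)
    if (sum(keep) < 2L) next
    m <- mean(v[keep]); s <- stats::sd(v[keep])
    if (!is.finite(s) || s == 0) next
    out[idx] <- pmin(m + k * s, pmax(m - k * s, v))
  }
  out
}

#' Preprocess one raw trial
#'
#' Runs the full chain: segmentation, positional filtering of the head and
#' controller series, gaze filtering at both cutoffs, world/egocentric
#' angles, great-circle kinematics of gaze and of the ball's head-centric
#' direction, and the missing-data QC decision on the segmented window.
#'
#' @param raw Trial data.frame in the trial schema.
#' @param cfg A \code{\link{preprocess_config}}.
#' @param fs Sampling rate, Hz.
#' @return List of class \code{"ivr_recording"} with the raw data, landmark
#'   frames, filtered series, angle and kinematic tables, missing mask and QC
#'   decision.
#' @export
preprocess_trial <- function(raw, cfg = preprocess_config(), fs = 90) {
  seg <- segment_trial(raw, fs = fs)
  dt <- 1 / fs
  miss <- is.na(raw$gaze_dir_x) | raw$gaze_valid == 0L
  gdir <- as.matrix(raw[, c("gaze_dir_x", "gaze_dir_y", "gaze_dir_z")])
  gdir[miss, ] <- NA_real_
  g50 <- suppressWarnings(
    unit_rows_safe(filter_gaze(gdir, "saccade", fs = fs, cfg = cfg)))
  g15 <- unit_rows_safe(filter_gaze(gdir, "position", fs = fs, cfg = cfg))
  hq <- as.matrix(raw[, c("head_qw", "head_qx", "head_qy", "head_qz")])
  angles <- to_world_angles(g15, hq)
  kin50 <- angular_kinematics(g50, dt)
  origin <- as.matrix(raw[, c("gaze_origin_x", "gaze_origin_y", "gaze_origin_z")])
  bdir <- as.matrix(raw[, c("ball_x", "ball_y", "ball_z")]) - origin
  ball_kin <- angular_kinematics(bdir, dt)
  ctrl_f <- filter_positional(as.matrix(raw[, c("ctrl_x", "ctrl_y", "ctrl_z")]),
                              cutoff = cfg$positional_cutoff_hz, fs = fs,
                              order = cfg$butter_order)
  head_f <- filter_positional(as.matrix(raw[, c("head_x", "head_y", "head_z")]),
                              cutoff = cfg$positional_cutoff_hz, fs = fs,
                              order = cfg$butter_order)
  window <- if (!is.na(seg$release_frame) && !is.na(seg$contact_frame))
    seq(seg$release_frame, seg$contact_frame) else seq_len(nrow(raw))
  qc <- exclude_trial(miss[window], fs = fs, cfg = cfg)
  structure(list(raw = raw, fs = fs,
                 release_frame = seg$release_frame,
                 bounce_frame = seg$bounce_frame,
                 contact_frame = seg$contact_frame,
                 contact_kind = seg$contact_kind,
                 segment_flags = seg$qc_flags,
                 gaze50 = g50, gaze15 = g15,
                 angles = angles, kinematics = kin50,
                 ball_kinematics = ball_kin,
                 ctrl_filtered = ctrl_f, head_filtered = head_f,
                 missing = miss, window = window, qc = qc),
            class = "ivr_recording")
}

unit_rows_safe <- function(m) {
  n <- sqrt(rowSums(m^2))
  bad <- is.na(n) | n < 1e-9
  m[!bad, ] <- m[!bad, , drop = FALSE] / n[!bad]
  m
}
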