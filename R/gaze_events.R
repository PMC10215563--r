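# Saccade and fixation detection from filtered gaze kinematics. Saccades:
# adaptive acceleration threshold (5 x the trial's median absolute
# acceleration) gated by velocity (> 40 deg/s for five consecutive frames and
# at least 20% above the ball's angular velocity), endpoints refined to the
# flanking acceleration extrema, candidates adjacent to missing data
# rejected. Fixations: dispersion-threshold (I-DT) sweep, 3 deg dispersion
# for at least 100 ms, windows split at missing samples.
#
# Frames are 1-based; event intervals are half-open [onset, offset).

#' Detect saccades from gaze kinematics
#'
#' @param kinematics data.frame with \code{velocity} (deg/s) and
#'   \code{acceleration} (deg/s^2) from the saccade-purpose (50 Hz) filtered
#'   gaze, as from \code{\link{angular_kinematics}}.
#' @param ball_velocity Ball angular velocity (deg/s), same length.
#' @param missing Logical missing-sample mask, same length.
#' @param fs Sampling rate, Hz.
#' @param vel_threshold Minimum gaze velocity, deg/s.
#' @param min_consecutive Consecutive frames the velocity gates must hold.
#' @param ball_factor Gaze velocity must be at least this multiple of the
#'   ball's.
#' @param acc_factor Acceleration threshold in multiples of the median
#'   absolute acceleration.
#' @param merge_gap_frames Adjacent candidates separated by at most this many
#'   sub-threshold frames are merged (the acceleration magnitude necessarily
#'   dips near the velocity peak, briefly splitting one saccade in two).
#' @param extend_ms Endpoint-refinement search bound beyond the candidate, ms.
#' @return data.frame of class \code{"ivr_saccades"}: \code{onset},
#'   \code{offset} (exclusive), \code{peak_velocity}, \code{amplitude}
#'   (path-integrated, deg). Zero rows (with a \code{qc_note} attribute) when
#'   the trial is unusable.
#' @export
detect_saccades <- function(kinematics, ball_velocity, missing, fs = 90,
                            vel_threshold = 40, min_consecutive = 5L,
                            ball_factor = 1.2, acc_factor = 5,
                            merge_gap_frames = 3L, extend_ms = 50) {
  n <- nrow(kinematics)
  vel <- kinematics$velocity
  acc <- kinematics$acceleration
  empty <- structure(data.frame(onset = integer(), offset = integer(),
                                peak_velocity = numeric(), amplitude = numeric()),
                     class = c("ivr_saccades", "data.frame"))
  usable <- !missing & !is.na(acc)
  if (!any(usable)) {
    attr(empty, "qc_note") <- "all samples missing"
    return(empty)
  }
  mad_acc <- stats::median(abs(acc[usable]))
  if (!is.finite(mad_acc) || mad_acc <= 0) {
    attr(empty, "qc_note") <- "degenerate acceleration signal"
    return(empty)
  }
  cand <- !is.na(acc) & abs(acc) > acc_factor * mad_acc & !missing
  runs <- na_runs(cand)
  if (!length(runs)) return(empty)
  # merge candidates separated by small gaps
  merged <- list(range(runs[[1L]]))
  for (r in runs[-1L]) {
    last <- merged[[length(merged)]]
    if (min(r) - last[2L] - 1L <= merge_gap_frames)
      merged[[length(merged)]] <- c(last[1L], max(r))
    else merged[[length(merged) + 1L]] <- range(r)
  }
  ext <- round(extend_ms / 1000 * fs)
  dt <- 1 / fs
  out <- list()
  prev_end <- 1L
  for (m in merged) {
    a <- m[1L]; b <- m[2L]
    idx <- a:b
    gate <- !is.na(vel[idx]) & vel[idx] > vel_threshold &
      vel[idx] >= ball_factor * ball_velocity[idx] & !missing[idx]
    r <- rle(gate)
    if (!any(r$values & r$lengths >= min_consecutive)) next
    # candidates preceded or followed by (or containing) missing data are
    # rejected before refinement
    if (a - 1L >= 1L && missing[a - 1L]) next
    if (b + 1L <= n && missing[b + 1L]) next
    if (any(missing[a:b])) next
    # refine endpoints from the velocity peak outward to where the velocity
    # re-enters the local baseline (median + 3 robust SDs of the flanking
    # pursuit/fixation samples, floored at 5 deg/s); this finds the edge of
    # the flanking acceleration extrema while trimming pursuit samples whose
    # acceleration also cleared the threshold
    pk <- idx[which.max(vel[idx])]
    loc_thr <- function(win) {
      v <- vel[win[win >= 1L & win <= n]]
      v <- v[!is.na(v)]
      if (length(v) < 3L) return(5)
      max(stats::median(v) + 3 * stats::mad(v), 5)
    }
    thr_on <- loc_thr((a - 18L):(a - 3L))
    thr_off <- loc_thr((b + 3L):(b + 18L))
    w0 <- max(prev_end + 1L, a - 2L * ext)
    onset <- pk
    while (onset - 1L >= w0 && !is.na(vel[onset - 1L]) &&
           vel[onset - 1L] > thr_on)
      onset <- onset - 1L
    w1 <- min(n, b + 2L * ext)
    off_last <- pk
    while (off_last + 1L <= w1 && !is.na(vel[off_last + 1L]) &&
           vel[off_last + 1L] > thr_off)
      off_last <- off_last + 1L
    offset <- off_last + 1L             # exclusive
    # reject events flanked by missing data
    before <- onset - 1L
    if (before >= 1L && missing[before]) next
    if (offset <= n && missing[offset]) next
    if (any(missing[onset:(offset - 1L)])) next
    seg <- onset:(offset - 1L)
    out[[length(out) + 1L]] <- data.frame(
      onset = onset, offset = offset,
      peak_velocity = max(vel[seg], na.rm = TRUE),
      amplitude = sum(vel[seg], na.rm = TRUE) * dt)
    prev_end <- offset - 1L
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  class(res) <- c("ivr_saccades", "data.frame")
  res
}

# dispersion of a window: sum of yaw and pitch ranges (classic I-DT), or the
# maximum pairwise great-circle separation
window_dispersion <- function(yaw, pitch, metric = "idt") {
  if (metric == "idt")
    return((max(yaw) - min(yaw)) + (max(pitch) - min(pitch)))
  d <- angles_to_dir(yaw, pitch)
  mx <- 0
  for (i in seq_len(nrow(d) - 1L))
    mx <- max(mx, max(great_circle_deg(
      d[rep(i, nrow(d) - i), , drop = FALSE],
      d[(i + 1L):nrow(d), , drop = FALSE])))
  mx
}

#' Detect fixations with a dispersion-threshold (I-DT) sweep
#'
#' Grows a window while its dispersion stays within the threshold and emits a
#' fixation when the window lasts at least the minimum duration. Dispersion
#' is the sum of the yaw and pitch ranges (\code{metric = "idt"}) or the
#' maximum pairwise great-circle separation (\code{metric = "pairwise"}).
#' Windows never span missing samples.
#'
#' @param angles data.frame with \code{yaw} and \code{pitch} (deg) from the
#'   position-purpose (15 Hz) filtered gaze; an \code{ego_pitch} column, if
#'   present, is averaged into the output.
#' @param missing Logical missing-sample mask.
#' @param fs Sampling rate, Hz.
#' @param dispersion_max Dispersion threshold, deg.
#' @param min_duration_ms Minimum fixation duration, ms.
#' @param metric Dispersion metric (see above).
#' @return data.frame of class \code{"ivr_fixations"}: \code{onset},
#'   \code{offset} (exclusive), \code{centroid_yaw}, \code{centroid_pitch},
#'   \code{dispersion}, \code{duration} (s), \code{mean_ego_pitch}.
#' @export
detect_fixations <- function(angles, missing = rep(FALSE, nrow(angles)),
                             fs = 90, dispersion_max = 3,
                             min_duration_ms = 100,
                             metric = c("idt", "pairwise")) {
  metric <- match.arg(metric)
  yaw <- angles$yaw; pitch <- angles$pitch
  ego <- if ("ego_pitch" %in% names(angles)) angles$ego_pitch else rep(NA_real_, length(yaw))
  ok <- !missing & !is.na(yaw) & !is.na(pitch)
  minlen <- ceiling(min_duration_ms / 1000 * fs)
  out <- list()
  for (run in na_runs(ok)) {
    s <- run[1L]; e <- run[length(run)]
    i <- s
    while (i + minlen - 1L <= e) {
      w0 <- i:(i + minlen - 1L)
      if (window_dispersion(yaw[w0], pitch[w0], metric) <= dispersion_max) {
        j <- i + minlen - 1L
        if (metric == "idt") {
          # incremental range updates while growing the window
          y_lo <- min(yaw[w0]); y_hi <- max(yaw[w0])
          p_lo <- min(pitch[w0]); p_hi <- max(pitch[w0])
          while (j + 1L <= e) {
            ny_lo <- min(y_lo, yaw[j + 1L]); ny_hi <- max(y_hi, yaw[j + 1L])
            np_lo <- min(p_lo, pitch[j + 1L]); np_hi <- max(p_hi, pitch[j + 1L])
            if ((ny_hi - ny_lo) + (np_hi - np_lo) > dispersion_max) break
            y_lo <- ny_lo; y_hi <- ny_hi; p_lo <- np_lo; p_hi <- np_hi
            j <- j + 1L
          }
        } else {
          while (j + 1L <= e &&
                 window_dispersion(yaw[i:(j + 1L)], pitch[i:(j + 1L)],
                                   metric) <= dispersion_max)
            j <- j + 1L
        }
        w <- i:j
        out[[length(out) + 1L]] <- data.frame(
          onset = i, offset = j + 1L,
          centroid_yaw = mean(yaw[w]), centroid_pitch = mean(pitch[w]),
          dispersion = window_dispersion(yaw[w], pitch[w], metric),
          duration = length(w) / fs,
          mean_ego_pitch = mean(ego[w]))
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(onset = integer(), offset = integer(),
                      centroid_yaw = numeric(), centroid_pitch = numeric(),
                      dispersion = numeric(), duration = numeric(),
                      mean_ego_pitch = numeric())
  } else {
    res <- do.call(rbind, out)
  }
  class(res) <- c("ivr_fixations", "data.frame")
  res
}
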