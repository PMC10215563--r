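# Per-trial dependent measures: interception outcome (sphere-vs-oriented-box
# collision with the exaggerated racquet thickness), the bounce fixation's
# egocentric pitch and duration, and peak swing velocity over the foreswing;
# plus assembly of the probe- and trial-level analysis tables (prior-error
# coding and carried-forward appraisals).

#' Select the bounce fixation
#'
#' The fixation whose interval contains the bounce frame; otherwise the
#' latest fixation ending before the bounce; \code{NULL} if neither exists.
#'
#' @param fixations \code{\link{detect_fixations}} output (ordered by onset).
#' @param bounce_frame Bounce frame index.
#' @return One-row data.frame, or \code{NULL}.
#' @export
bounce_fixation <- function(fixations, bounce_frame) {
  if (is.null(fixations) || !nrow(fixations) || is.na(bounce_frame)) return(NULL)
  covering <- fixations$onset <= bounce_frame & fixations$offset > bounce_frame
  if (any(covering)) return(fixations[which(covering)[1L], , drop = FALSE])
  before <- fixations$offset <= bounce_frame
  if (!any(before)) return(NULL)
  fixations[max(which(before)), , drop = FALSE]
}

#' Bounce-fixation pitch and duration
#'
#' @param fix One-row fixation (from \code{\link{bounce_fixation}}).
#' @param ego_pitch Egocentric pitch series, deg.
#' @param fs Sampling rate, Hz.
#' @return List with \code{pitch} (mean egocentric pitch over
#'   \code{[onset, offset)}, deg) and \code{duration} (s).
#' @export
bounce_fixation_metrics <- function(fix, ego_pitch, fs = 90) {
  stopifnot(!is.null(fix), nrow(fix) == 1L)
  idx <- fix$onset:(fix$offset - 1L)
  list(pitch = mean(ego_pitch[idx], na.rm = TRUE),
       duration = (fix$offset - fix$onset) / fs)
}

#' Peak swing velocity over the foreswing
#'
#' The foreswing is the contiguous run of frames immediately before contact
#' in which the controller moves toward the interception point (positive
#' velocity component toward it), starting at the last sign change of that
#' component. Speed per frame is the Euclidean norm of the positional
#' differential times the sampling rate.
#'
#' @param ctrl n x 3 controller positions (10 Hz-filtered), m.
#' @param contact_frame Contact frame index.
#' @param aim Interception point (length-3), m; defaults to the ball position
#'   at contact if \code{ball} is given.
#' @param ball Optional n x 3 ball positions used to derive \code{aim}.
#' @param fs Sampling rate, Hz.
#' @return List: \code{peak} (m/s, NA when no foreswing is detected),
#'   \code{foreswing_onset}, \code{flag} (NA or "no_foreswing").
#' @export
peak_swing_velocity <- function(ctrl, contact_frame, aim = NULL, ball = NULL,
                                fs = 90) {
  if (is.null(aim)) {
    stopifnot(!is.null(ball))
    aim <- as.numeric(ball[contact_frame, ])
  }
  k <- contact_frame
  v <- (ctrl[2:k, , drop = FALSE] - ctrl[1:(k - 1L), , drop = FALSE]) * fs
  to_aim <- matrix(aim, k - 1L, 3L, byrow = TRUE) - ctrl[1:(k - 1L), , drop = FALSE]
  to_aim <- unit_rows_safe(to_aim)
  comp <- rowSums(v * to_aim)           # closing component toward the aim
  speed <- sqrt(rowSums(v^2))
  if (all(speed <= 1e-9, na.rm = TRUE))
    return(list(peak = 0, foreswing_onset = NA_integer_, flag = NA_character_))
  eps <- 1e-6
  # speeds below this are treated as no motion (rest holds, filter ringing)
  thr <- max(0.05 * max(speed[max(1L, k - 1L - fs):(k - 1L)], na.rm = TRUE),
             1e-3)
  # last clear approach frame before contact (trailing frames can point away
  # once the racquet passes its closest approach on missed swings)
  j <- k - 1L
  while (j >= 1L && (is.na(comp[j]) || comp[j] <= eps || speed[j] <= thr))
    j <- j - 1L
  if (j < 1L)
    return(list(peak = NA_real_, foreswing_onset = NA_integer_,
                flag = "no_foreswing"))
  # extend backward to the last sign change of the closing component
  i <- j
  while (i >= 1L && !is.na(comp[i]) && !(comp[i] < -eps && speed[i] > thr))
    i <- i - 1L
  fore <- (i + 1L):j
  list(peak = max(speed[fore]), foreswing_onset = i + 2L,
       flag = NA_character_)
}

#' Interception outcome from ball and racquet pose series
#'
#' TRUE iff the ball (a sphere of the configured radius) intersects the
#' racquet's oriented box -- the visible face extent with the exaggerated
#' collision thickness -- on any frame (inclusive boundary).
#'
#' @param ball n x 3 ball positions, m.
#' @param ctrl_pos n x 3 controller positions, m.
#' @param ctrl_quat n x 4 controller orientations (w, x, y, z).
#' @param cfg A \code{\link{physics_config}} (racquet extent, collision
#'   thickness, ball diameter).
#' @return Logical.
#' @export
interception_outcome <- function(ball, ctrl_pos, ctrl_quat,
                                 cfg = physics_config()) {
  half <- c(cfg$racquet_extent[1] / 2, cfg$racquet_extent[2] / 2,
            cfg$collision_thickness / 2)
  r <- cfg$ball_diameter / 2
  n <- nrow(ball)
  qkey <- apply(round(ctrl_quat, 12L), 1L, paste, collapse = ",")
  hit <- FALSE
  for (key in unique(qkey)) {
    idx <- which(qkey == key)
    R <- quat_to_mat(ctrl_quat[idx[1L], ])
    local <- (ball[idx, , drop = FALSE] - ctrl_pos[idx, , drop = FALSE]) %*% R
    clamped <- pmin(pmax(local, rep(-half, each = length(idx))),
                    rep(half, each = length(idx)))
    d2 <- rowSums((local - clamped)^2)
    # inclusive boundary, robust to representation error
    if (any(d2 <= r^2 + 1e-9)) { hit <- TRUE; break }
  }
  hit
}

#' Compute all per-trial metrics for a preprocessed recording
#'
#' @param rec An \code{\link{preprocess_trial}} result.
#' @param cfg A \code{\link{physics_config}}.
#' @return One-row data.frame: \code{intercepted},
#'   \code{bounce_fix_pitch}, \code{bounce_fix_duration},
#'   \code{peak_swing_velocity}, \code{gaze_excluded}, \code{qc}.
#' @export
trial_metrics <- function(rec, cfg = physics_config()) {
  raw <- rec$raw
  ballm <- as.matrix(raw[, c("ball_x", "ball_y", "ball_z")])
  ctrl_raw <- as.matrix(raw[, c("ctrl_x", "ctrl_y", "ctrl_z")])
  cq <- as.matrix(raw[, c("ctrl_qw", "ctrl_qx", "ctrl_qy", "ctrl_qz")])
  intercepted <- interception_outcome(ballm, ctrl_raw, cq, cfg)
  pitch <- NA_real_; dur <- NA_real_
  excluded <- isTRUE(rec$qc$excluded)
  if (!excluded && !is.na(rec$bounce_frame)) {
    fx <- detect_fixations(rec$angles, missing = rec$missing, fs = rec$fs)
    bf <- bounce_fixation(fx, rec$bounce_frame)
    if (!is.null(bf)) {
      bm <- bounce_fixation_metrics(bf, rec$angles$ego_pitch, fs = rec$fs)
      pitch <- bm$pitch; dur <- bm$duration
    }
  }
  psv <- if (!is.na(rec$contact_frame))
    peak_swing_velocity(rec$ctrl_filtered, rec$contact_frame, ball = ballm,
                        fs = rec$fs)
  else list(peak = NA_real_, flag = "no_contact")
  data.frame(intercepted = intercepted,
             bounce_fix_pitch = pitch,
             bounce_fix_duration = dur,
             peak_swing_velocity = psv$peak,
             gaze_excluded = excluded,
             qc = paste(stats::na.omit(c(rec$qc$reason, psv$flag,
                                         rec$segment_flags)), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Assemble the probe- and trial-level analysis tables
#'
#' The probe table has one row per probe (appraisals and anxiety with
#' condition labels). The trial table has one row per trial with
#' \code{prior_errors} -- the run of consecutive preceding 'miss' feedback
#' calls, capped at 4 and reset by any 'hit' call -- and the most recent
#' probe's anxiety, POF and COF carried forward (NA before the first probe).
#' Blocks are traversed in their completed order.
#'
#' @param trials Trial manifest table (participant, block, trial,
#'   feedback_call, ...; \code{hit_truth} or merged metric columns).
#' @param probes Probe table with \code{pof}, \code{cof}, \code{anxiety}.
#' @param metrics Optional data.frame of \code{\link{trial_metrics}} rows
#'   aligned with \code{trials}.
#' @param error_cap Cap on the prior-error count.
#' @return List with \code{probe_table} and \code{trial_table}.
#' @export
assemble_analysis_table <- function(trials, probes, metrics = NULL,
                                    error_cap = 4L) {
  tt <- trials
  if (!is.null(metrics)) tt <- cbind(tt, metrics)
  if (!"intercepted" %in% names(tt)) {
    if (!"hit_truth" %in% names(tt))
      stop("trial table needs `intercepted` metrics or `hit_truth`",
           call. = FALSE)
    tt$intercepted <- tt$hit_truth == 1L
  }
  tt <- tt[order(tt$participant, tt$block, tt$trial), ]
  pr <- probes[order(probes$participant, probes$block, probes$trial), ]
  tt$prior_errors <- NA_integer_
  tt$anxiety <- NA_real_
  tt$pof <- NA_real_
  tt$cof <- NA_real_
  for (pid in unique(tt$participant)) {
    rows <- which(tt$participant == pid)
    # consecutive preceding misses, reset by hits, per block
    for (b in unique(tt$block[rows])) {
      br <- rows[tt$block[rows] == b]
      run <- 0L
      for (j in seq_along(br)) {
        tt$prior_errors[br[j]] <- min(run, error_cap)
        run <- if (tt$feedback_call[br[j]] == "miss") run + 1L else 0L
      }
    }
    # carry the most recent probe's reports forward across the session
    pp <- pr[pr$participant == pid, ]
    if (!nrow(pp)) next
    pkey <- pp$block * 10000 + pp$trial
    tkey <- tt$block[rows] * 10000 + tt$trial[rows]
    idx <- findInterval(tkey - 0.5, pkey)  # latest probe strictly before
    has <- idx >= 1L
    tt$anxiety[rows[has]] <- pp$anxiety[idx[has]]
    tt$pof[rows[has]] <- pp$pof[idx[has]]
    tt$cof[rows[has]] <- pp$cof[idx[has]]
  }
  list(probe_table = pr, trial_table = tt)
}
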