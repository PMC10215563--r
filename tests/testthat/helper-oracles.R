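# Shared fixtures and independent oracles used across the suite.

# gaze/dropout settings that make generator ground truth exact
quiet_gaze <- function(...) {
  gaze_config(fixation_jitter_sd = 0, dropout_rate = 0, ...)
}

# a cached noise-free hit trial (built once per test run)
quiet_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_trial("normal", hit = TRUE, gaze = quiet_gaze(),
                               seed = 1L)
    cache
  }
})

# Exhaustive dispersion-threshold fixation oracle: for every window start,
# recompute the dispersion from scratch while extending (O(n^2)); same
# emit/advance semantics as the spec'd I-DT sweep but an independent code
# path with no incremental state.
brute_force_idt <- function(yaw, pitch, missing = rep(FALSE, length(yaw)),
                            fs = 90, dispersion_max = 3,
                            min_duration_ms = 100) {
  disp <- function(idx) {
    (max(yaw[idx]) - min(yaw[idx])) + (max(pitch[idx]) - min(pitch[idx]))
  }
  ok <- !missing & !is.na(yaw) & !is.na(pitch)
  minlen <- ceiling(min_duration_ms / 1000 * fs)
  out <- list()
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    i <- s
    while (i + minlen - 1L <= e) {
      if (disp(i:(i + minlen - 1L)) <= dispersion_max) {
        j <- i + minlen - 1L
        while (j + 1L <= e && disp(i:(j + 1L)) <= dispersion_max) j <- j + 1L
        out[[length(out) + 1L]] <- c(onset = i, offset = j + 1L)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out)) return(data.frame(onset = integer(), offset = integer()))
  as.data.frame(do.call(rbind, out))
}

# match detected saccades against generator ground truth within a window
saccade_score <- function(detected, truth_events, from, to) {
  truth <- truth_events[truth_events$class == "saccade" &
                          truth_events$onset >= from &
                          truth_events$onset <= to, ]
  tp <- 0L; fn <- 0L; max_onset_err <- 0L
  for (k in seq_len(nrow(truth))) {
    hit <- which(detected$onset < truth$offset[k] &
                   detected$offset > truth$onset[k])
    if (length(hit) == 1L) {
      tp <- tp + 1L
      max_onset_err <- max(max_onset_err,
                           abs(detected$onset[hit] - truth$onset[k]))
    } else fn <- fn + 1L
  }
  fp <- sum(vapply(seq_len(nrow(detected)), function(k) {
    !any(detected$onset[k] < truth$offset & detected$offset[k] > truth$onset)
  }, logical(1L)))
  list(recall = if (tp + fn) tp / (tp + fn) else NA_real_,
       precision = if (nrow(detected)) (nrow(detected) - fp) / nrow(detected) else NA_real_,
       max_onset_err = max_onset_err, n_truth = nrow(truth))
}
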