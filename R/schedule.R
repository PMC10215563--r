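# Bogus hit/miss feedback schedules and probe placement. Each 72-trial block
# delivers non-contingent feedback at a fixed success ratio (58% in the
# low-failure-feedback condition, 42% in the high), with six probe trials per
# block chosen so that three follow a 'hit' call, three follow a 'miss' call,
# and the running hit proportion at every probe matches the block's nominal
# ratio to within rounding.

#' Build a bogus-feedback schedule for one block
#'
#' Feedback calls are a seeded permutation of the required hit/miss multiset;
#' probe trials are then selected (rejection sampling with a retry cap) to
#' satisfy the matching constraints. Ball types are a seeded permutation with
#' p(normal) = 0.67 over the block.
#'
#' @param feedback \code{"low"} (58% hits) or \code{"high"} (42% hits);
#'   levels refer to the probability of *failure* feedback.
#' @param n_trials Trials in the block (>= 12).
#' @param n_probes Probe trials per block.
#' @param p_normal Proportion of normal-elasticity balls.
#' @param seed Integer seed.
#' @param max_retries Retry cap for the constraint search.
#' @return A list of class \code{"ivr_schedule"}: \code{condition_feedback},
#'   \code{n_trials}, \code{feedback_calls} (character "hit"/"miss"),
#'   \code{probe_trials} (sorted indices), \code{ball_types}, \code{hit_prop}.
#' @export
build_feedback_schedule <- function(feedback = c("low", "high"), n_trials = 72L,
                                    n_probes = 6L, p_normal = 0.67,
                                    seed = 1L, max_retries = 10000L) {
  feedback <- match.arg(feedback)
  n_trials <- as.integer(n_trials)
  if (n_trials < 12L)
    stop("`n_trials` must be >= 12", call. = FALSE)
  p_hit <- if (feedback == "low") 0.58 else 0.42
  n_hit <- round(p_hit * n_trials)
  set.seed(seed)

  calls_ok <- NULL
  probes_ok <- NULL
  for (try in seq_len(max_retries)) {
    calls <- sample(rep(c("hit", "miss"), c(n_hit, n_trials - n_hit)))
    cumhit <- cumsum(calls == "hit")
    trials <- seq_len(n_trials)
    # candidate probe positions: running hit count within +-1 of the rounded
    # nominal count; probes sit late enough that the ratio is meaningful
    balanced <- abs(cumhit - round(p_hit * trials)) <= 1
    cand <- trials[balanced & trials >= 6L & trials <= n_trials]
    ch <- cand[calls[cand] == "hit"]
    cm <- cand[calls[cand] == "miss"]
    if (length(ch) >= n_probes / 2 && length(cm) >= n_probes / 2) {
      probes <- sort(c(sample(ch, n_probes / 2), sample(cm, n_probes / 2)))
      if (!anyDuplicated(probes)) {
        calls_ok <- calls
        probes_ok <- probes
        break
      }
    }
  }
  if (is.null(calls_ok))
    stop(sprintf("could not satisfy probe constraints for n_trials = %d within %d retries",
                 n_trials, max_retries), call. = FALSE)

  n_normal <- round(p_normal * n_trials)
  ball_types <- sample(rep(c("normal", "elastic"), c(n_normal, n_trials - n_normal)))

  structure(list(condition_feedback = feedback,
                 n_trials = n_trials,
                 feedback_calls = calls_ok,
                 probe_trials = probes_ok,
                 ball_types = ball_types,
                 hit_prop = p_hit),
            class = "ivr_schedule")
}
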