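# Monte-Carlo power for the probe-design condition model: simulate
# random-intercept datasets from known variance components and a
# standardized fixed effect, refit the condition model, and count rejections
# of the focal coefficient.

#' Simulate power for the condition model across sample sizes
#'
#' For each sample size, \code{reps} datasets are generated from a
#' participant-random-intercept model on a standardized outcome scale
#' (random-intercept variance \code{icc}, residual variance \code{1 - icc},
#' total variance 1, so \code{effect} is a standardized mean difference).
#' Each participant contributes \code{obs_per_participant} observations
#' split evenly across the 2x2 pressure-by-feedback cells. The condition
#' model (\code{\link{fit_condition_model}} specification) is refitted to
#' each dataset and power is the fraction of replicates whose focal
#' coefficient has Wald p < \code{alpha}.
#'
#' @param n_grid Integer vector of participant counts.
#' @param effect Standardized effect on the focal indicator.
#' @param obs_per_participant Observations per participant (multiple of 4).
#' @param icc Intraclass correlation (random-intercept share of variance).
#' @param reps Monte-Carlo replicates per sample size (>= 50).
#' @param alpha Significance level.
#' @param focal Focal coefficient: \code{"feedback"}, \code{"pressure"} or
#'   \code{"interaction"}.
#' @param seed Integer seed.
#' @return data.frame with \code{n}, \code{power}, \code{mc_se} (binomial
#'   Monte-Carlo standard error) and \code{reps}.
#' @export
simulate_power <- function(n_grid = 43L, effect = 0.2,
                           obs_per_participant = 24L, icc = 0.5,
                           reps = 200L, alpha = 0.05,
                           focal = c("feedback", "pressure", "interaction"),
                           seed = 1L) {
  focal <- match.arg(focal)
  if (reps < 50L) stop("`reps` must be >= 50", call. = FALSE)
  if (icc < 0 || icc >= 1) stop("`icc` must be in [0, 1)", call. = FALSE)
  per_cell <- obs_per_participant / 4
  if (per_cell != round(per_cell))
    stop("`obs_per_participant` must be a multiple of 4", call. = FALSE)
  term <- switch(focal, feedback = "feedback01", pressure = "pressure01",
                 interaction = "pressure01:feedback01")
  sd_u <- sqrt(icc)
  sd_e <- sqrt(1 - icc)
  out <- lapply(n_grid, function(n) {
    cell <- expand.grid(pressure01 = 0:1, feedback01 = 0:1)
    base <- cell[rep(seq_len(4L), each = per_cell), ]
    rej <- logical(reps)
    for (r in seq_len(reps)) {
      set.seed(derive_seed(seed, n * 100000L + r))
      d <- base[rep(seq_len(nrow(base)), n), ]
      d$participant <- rep(seq_len(n), each = nrow(base))
      u <- stats::rnorm(n, 0, sd_u)
      x <- switch(focal, feedback = d$feedback01, pressure = d$pressure01,
                  interaction = d$pressure01 * d$feedback01)
      d$y <- effect * x + u[d$participant] +
        stats::rnorm(nrow(d), 0, sd_e)
      fit <- suppressMessages(
        lme4::lmer(y ~ pressure01 * feedback01 + (1 | participant),
                   data = d, REML = TRUE))
      beta <- lme4::fixef(fit)[term]
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))[term]
      p <- 2 * stats::pnorm(-abs(beta / se))
      rej[r] <- is.finite(p) && p < alpha
    }
    pw <- mean(rej)
    data.frame(n = n, power = pw,
               mc_se = sqrt(pw * (1 - pw) / reps), reps = reps)
  })
  do.call(rbind, out)
}
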