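# Mixed-effects analysis recipes. Estimation is delegated to lme4 (REML
# lmer for Gaussian outcomes, Laplace glmer for the logistic outcome); this
# module owns model specification (0/1 indicator coding with the
# low-pressure/low-feedback reference), confidence intervals and p-values
# (Satterthwaite t via lmerTest for linear models, Wald for logistic),
# standardized betas, marginal and conditional R-squared by variance
# decomposition, Holm-corrected follow-up t-tests and Monte-Carlo power
# curves.

new_ivr_fit <- function(fit, formula_str, data, family, outcome) {
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  if (family == "gaussian" && inherits(fit, "lmerModLmerTest")) {
    ct <- stats::coef(summary(fit))
    df <- ct[, "df"]
    p <- ct[, "Pr(>|t|)"]
    q <- stats::qt(0.975, df)
  } else {
    df <- rep(Inf, length(beta))
    p <- 2 * stats::pnorm(-abs(beta / se))
    q <- rep(stats::qnorm(0.975), length(beta))
  }
  vc <- lme4::VarCorr(fit)
  var_u <- as.numeric(vc[[1L]][1L, 1L])
  var_e <- if (family == "gaussian") attr(vc, "sc")^2 else pi^2 / 3
  X <- stats::model.matrix(fit)
  var_f <- stats::var(as.numeric(X %*% beta))
  denom <- var_f + var_u + var_e
  r2_marginal <- var_f / denom
  r2_conditional <- (var_f + var_u) / denom
  sd_y <- if (family == "gaussian") stats::sd(stats::model.frame(fit)[[1L]])
          else sqrt(denom)
  std <- vapply(seq_along(beta), function(j) {
    if (names(beta)[j] == "(Intercept)") return(NA_real_)
    sx <- stats::sd(X[, names(beta)[j]])
    if (sd_y == 0) stop("standardized betas: outcome has zero SD", call. = FALSE)
    unname(beta[j] * sx / sd_y)
  }, numeric(1L))
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), df = unname(df),
                      ci_lower = unname(beta - q * se),
                      ci_upper = unname(beta + q * se),
                      p_value = unname(p),
                      std_beta = std,
                      effect_label = effect_size_label(std),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(formula = formula_str, family = family, outcome = outcome,
                 coefficients = coefs,
                 ranef_variance = var_u, residual_variance = var_e,
                 r2_marginal = r2_marginal, r2_conditional = r2_conditional,
                 n_obs = nrow(X),
                 n_groups = lme4::ngrps(fit)[[1L]],
                 singular = lme4::isSingular(fit),
                 fit = fit),
            class = "ivr_fit")
}

#' Effect-size label for a standardized beta
#'
#' Standardized betas are read like correlations: below 0.2 in magnitude is
#' weak, 0.2 to 0.5 moderate, above 0.5 strong (boundaries assigned upward).
#'
#' @param std Numeric vector of standardized betas.
#' @return Character vector ("weak"/"moderate"/"strong", NA preserved).
#' @export
effect_size_label <- function(std) {
  out <- rep(NA_character_, length(std))
  a <- abs(std)
  out[!is.na(a) & a < 0.2] <- "weak"
  out[!is.na(a) & a >= 0.2 & a <= 0.5] <- "moderate"
  out[!is.na(a) & a > 0.5] <- "strong"
  out
}

check_outcome <- function(y, what) {
  if (stats::sd(as.numeric(y), na.rm = TRUE) == 0)
    stop(what, " has zero variance; model cannot be estimated", call. = FALSE)
}

condition_indicators <- function(data) {
  data$pressure01 <- as.numeric(data$pressure == "high")
  data$feedback01 <- as.numeric(data$feedback == "high")
  data
}

#' Fit the condition model for a probe-level outcome
#'
#' A linear mixed model with pressure and feedback conditions (0/1
#' indicators, low/low reference) and their interaction as fixed effects and
#' a participant random intercept, fitted by REML. Singular fits are
#' reported via the \code{singular} field and a warning, never hidden.
#'
#' @param probe_table Probe-level data.frame with \code{participant},
#'   \code{pressure}, \code{feedback} and the outcome column.
#' @param outcome One of \code{"pof"}, \code{"cof"}, \code{"anxiety"}.
#' @return An object of class \code{"ivr_fit"}.
#' @export
fit_condition_model <- function(probe_table, outcome = c("pof", "cof", "anxiety")) {
  outcome <- match.arg(outcome)
  if (length(unique(probe_table$participant)) < 2L)
    stop("need at least 2 participants", call. = FALSE)
  check_outcome(probe_table[[outcome]], outcome)
  d <- condition_indicators(probe_table)
  f <- stats::as.formula(paste(outcome,
    "~ pressure01 * feedback01 + (1 | participant)"))
  fit <- lmerTest::lmer(f, data = d, REML = TRUE)
  out <- new_ivr_fit(fit, deparse(f), d, "gaussian", outcome)
  if (out$singular) warning("singular random-effect fit for ", outcome)
  out
}

#' Fit the appraisal model: anxiety from POF, COF and their interaction
#'
#' @param probe_table Probe-level data.frame with \code{pof}, \code{cof},
#'   \code{anxiety}, \code{participant}.
#' @return An \code{"ivr_fit"}.
#' @export
fit_appraisal_model <- function(probe_table) {
  check_outcome(probe_table$anxiety, "anxiety")
  if (stats::sd(probe_table$pof) == 0 && stats::sd(probe_table$cof) == 0)
    stop("POF and COF both have zero variance; appraisal model cannot be estimated",
         call. = FALSE)
  f <- anxiety ~ pof * cof + (1 | participant)
  fit <- lmerTest::lmer(f, data = probe_table, REML = TRUE)
  out <- new_ivr_fit(fit, deparse(f), probe_table, "gaussian", "anxiety")
  if (out$singular) warning("singular random-effect fit for anxiety ~ pof * cof")
  out
}

#' Fit an outcome model: gaze, swing or interception from momentary reports
#'
#' Fixed effects are anxiety, POF, COF and the POF:COF interaction with a
#' participant random intercept. Continuous outcomes use a REML linear mixed
#' model; \code{"intercepted"} uses a logistic mixed model.
#'
#' @param table Trial- or probe-aligned data.frame with the outcome plus
#'   \code{anxiety}, \code{pof}, \code{cof}, \code{participant}.
#' @param outcome One of \code{"bounce_fix_pitch"},
#'   \code{"bounce_fix_duration"}, \code{"peak_swing_velocity"},
#'   \code{"intercepted"}.
#' @return An \code{"ivr_fit"}.
#' @export
fit_outcome_model <- function(table, outcome = c("bounce_fix_pitch",
                                                 "bounce_fix_duration",
                                                 "peak_swing_velocity",
                                                 "intercepted")) {
  outcome <- match.arg(outcome)
  d <- table[!is.na(table[[outcome]]) & !is.na(table$anxiety) &
               !is.na(table$pof) & !is.na(table$cof), ]
  check_outcome(d[[outcome]], outcome)
  f <- stats::as.formula(paste(outcome,
    "~ anxiety + pof * cof + (1 | participant)"))
  if (outcome == "intercepted") {
    fit <- tryCatch(
      lme4::glmer(f, data = d, family = stats::binomial()),
      error = function(e) stop("logistic fit failed (possible separation): ",
                               conditionMessage(e), call. = FALSE))
    fam <- "binomial"
  } else {
    fit <- lmerTest::lmer(f, data = d, REML = TRUE)
    fam <- "gaussian"
  }
  out <- new_ivr_fit(fit, deparse(f), d, fam, outcome)
  if (out$singular) warning("singular random-effect fit for ", outcome)
  out
}

#' Fit the error-dependency model
#'
#' Logistic mixed model of true interception on the number of consecutive
#' preceding fed-back errors (0-4), the carried-forward anxiety score, and
#' their interaction, with a participant random intercept. Trials before the
#' first probe (no carried anxiety) are dropped.
#'
#' @param trial_table Trial-level data.frame with \code{intercepted},
#'   \code{prior_errors}, \code{anxiety}, \code{participant}.
#' @return An \code{"ivr_fit"}.
#' @export
fit_error_dependency_model <- function(trial_table) {
  d <- trial_table[!is.na(trial_table$anxiety), ]
  check_outcome(d$intercepted, "intercepted")
  f <- intercepted ~ prior_errors * anxiety + (1 | participant)
  fit <- tryCatch(
    lme4::glmer(f, data = d, family = stats::binomial()),
    error = function(e) stop("logistic fit failed (possible separation): ",
                             conditionMessage(e), call. = FALSE))
  out <- new_ivr_fit(fit, deparse(f), d, "binomial", "intercepted")
  if (out$singular) warning("singular random-effect fit for error-dependency model")
  out
}

#' Marginal and conditional R-squared of a fit
#'
#' Variance decomposition: marginal R2 is the fixed-effect prediction
#' variance over the total (fixed + random-intercept + residual); the
#' conditional R2 adds the random-intercept variance to the numerator.
#' Logistic models use the latent-scale residual variance pi^2 / 3.
#'
#' @param fit An \code{"ivr_fit"}.
#' @return Named numeric: \code{marginal}, \code{conditional}.
#' @export
r_squared <- function(fit) {
  c(marginal = fit$r2_marginal, conditional = fit$r2_conditional)
}

#' Standardized betas of a fit
#'
#' Each fixed-effect coefficient times SD(predictor) / SD(outcome), with
#' full-sample SDs; interaction terms are standardized from their product
#' column. Logistic models use the latent-scale outcome SD
#' sqrt(var_fixed + var_random + pi^2/3) (an approximation, flagged in the
#' documentation).
#'
#' @param fit An \code{"ivr_fit"}.
#' @return data.frame with \code{term}, \code{std_beta},
#'   \code{effect_label}.
#' @export
standardized_betas <- function(fit) {
  fit$coefficients[, c("term", "std_beta", "effect_label")]
}

#' Holm step-down adjustment
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order (monotone, never smaller
#'   than raw).
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1L) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Holm-corrected follow-up paired t-tests
#'
#' Each contrast compares participant-level cell means of \code{outcome}
#' between the two levels of \code{factor}, optionally within one level of
#' the other condition factor; p-values are Holm-adjusted across contrasts.
#'
#' @param probe_table Probe-level data.frame.
#' @param outcome Outcome column name.
#' @param contrasts List of contrasts; each a list with \code{factor}
#'   ("pressure" or "feedback") and optional \code{within} (named character,
#'   e.g. \code{c(feedback = "high")}).
#' @return data.frame with one row per contrast: \code{label}, \code{t},
#'   \code{df}, \code{p_raw}, \code{p_adjusted}.
#' @export
holm_followups <- function(probe_table, outcome, contrasts) {
  stopifnot(length(contrasts) >= 1L)
  res <- lapply(contrasts, function(ct) {
    d <- probe_table
    lab <- ct$factor
    if (!is.null(ct$within)) {
      for (nm in names(ct$within)) d <- d[d[[nm]] == ct$within[[nm]], ]
      lab <- paste0(lab, " | ", paste(names(ct$within), ct$within,
                                      sep = "=", collapse = ","))
    }
    agg <- stats::aggregate(d[[outcome]],
                            by = list(participant = d$participant,
                                      level = d[[ct$factor]]),
                            FUN = mean)
    wide <- stats::reshape(agg, idvar = "participant", timevar = "level",
                           direction = "wide")
    x <- wide[["x.high"]]; y <- wide[["x.low"]]
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(label = lab, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out
}

#' @export
print.ivr_fit <- function(x, ...) {
  cat("Mixed-effects fit (", x$family, "): ", x$formula, "\n", sep = "")
  cat(sprintf("  %d observations, %d participants%s\n", x$n_obs, x$n_groups,
              if (x$singular) " [singular fit]" else ""))
  cf <- x$coefficients
  cf[, sapply(cf, is.numeric)] <- round(cf[, sapply(cf, is.numeric)], 4L)
  print(cf, row.names = FALSE)
  cat(sprintf("  random-intercept var %.4f, residual var %.4f\n",
              x$ranef_variance, x$residual_variance))
  cat(sprintf("  R2 marginal %.3f, conditional %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' @export
summary.ivr_fit <- function(object, ...) object$coefficients

#' @export
coef.ivr_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
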