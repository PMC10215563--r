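make_probes <- function(seed = 21, n = 30) {
  d <- probe_design(sprintf("P%02d", seq_len(n)), seed = seed)
  generate_selfreports(d, selfreport_truth(), seed = seed)
}

make_trials <- function(seed = 22, n = 20, n_trials = 24L) {
  cfg <- load_config()
  cfg$session <- session_config(n_trials = n_trials)
  s <- simulate_session(cfg, seed = seed, participants = n,
                        keep_series = FALSE)
  assemble_analysis_table(s$trials, s$probes)
}

test_that("condition and appraisal fits report coefficients, CIs and R2 consistently", {
  d <- make_probes()
  fit <- fit_condition_model(d, "pof")
  expect_s3_class(fit, "ivr_fit")
  cf <- fit$coefficients
  expect_setequal(cf$term, c("(Intercept)", "pressure01", "feedback01",
                             "pressure01:feedback01"))
  expect_true(all(cf$ci_lower <= cf$estimate & cf$estimate <= cf$ci_upper))
  r2 <- r_squared(fit)
  expect_gte(r2[["marginal"]], 0)
  expect_lte(r2[["marginal"]], r2[["conditional"]])
  expect_lte(r2[["conditional"]], 1)
  expect_equal(fit$n_groups, 30L)
  expect_equal(fit$n_obs, 720L)
  fita <- fit_appraisal_model(d)
  expect_setequal(fita$coefficients$term,
                  c("(Intercept)", "pof", "cof", "pof:cof"))
  expect_output(print(fit), "Mixed-effects fit")
})

test_that("degenerate inputs fail loudly", {
  d <- make_probes()
  d$pof <- 3
  expect_error(fit_condition_model(d, "pof"), "zero variance")
  d$cof <- 2
  expect_error(fit_appraisal_model(d), "zero variance")
  expect_error(fit_condition_model(d[d$participant == "P01", ], "anxiety"),
               "2 participants")
})

test_that("outcome and error-dependency logistic models fit and flag degeneracy", {
  tabs <- make_trials()
  tt <- tabs$trial_table
  fit <- fit_error_dependency_model(tt)
  expect_equal(fit$family, "binomial")
  expect_setequal(fit$coefficients$term,
                  c("(Intercept)", "prior_errors", "anxiety",
                    "prior_errors:anxiety"))
  expect_equal(fit$residual_variance, pi^2 / 3)
  # trials without carried anxiety are dropped
  expect_equal(fit$n_obs, sum(!is.na(tt$anxiety)))
  # all-intercepted data cannot be fitted
  tt2 <- tt
  tt2$intercepted <- TRUE
  expect_error(fit_error_dependency_model(tt2), "zero variance")
})

test_that("outcome models accept carried appraisals as predictors", {
  tabs <- make_trials(seed = 23)
  tt <- tabs$trial_table
  set.seed(1)
  tt$peak_swing_velocity <- 3 + 0.1 * tt$cof + stats::rnorm(nrow(tt), 0, 0.3)
  fit <- suppressWarnings(fit_outcome_model(tt, "peak_swing_velocity"))
  expect_s3_class(fit, "ivr_fit")
  expect_true("cof" %in% fit$coefficients$term)
  # a singular random effect (true ICC 0 here) is reported, not hidden
  fitl <- suppressWarnings(fit_outcome_model(tt, "intercepted"))
  expect_equal(fitl$family, "binomial")
})

test_that("standardized betas follow the SD-ratio identity and label cut-offs", {
  # construct data where sd(x) and sd(y) are controlled: y = b x + noise
  set.seed(9)
  n <- 2000
  d <- data.frame(participant = rep(sprintf("P%02d", 1:20), each = n / 20),
                  pressure = "low", feedback = "low")
  x <- stats::rnorm(n, 0, 1)
  d$pof <- x
  d$cof <- stats::rnorm(n, 0, 1e-2)
  d$anxiety <- 0.5 * x + stats::rnorm(n, 0, sqrt(1 - 0.25))
  fit <- suppressWarnings(fit_appraisal_model(d))
  sb <- standardized_betas(fit)
  b <- fit$coefficients[fit$coefficients$term == "pof", ]
  manual <- b$estimate * stats::sd(d$pof) / stats::sd(d$anxiety)
  expect_equal(sb$std_beta[sb$term == "pof"], manual, tolerance = 1e-9)
  expect_equal(sb$std_beta[sb$term == "pof"], 0.5, tolerance = 0.1)
  # label boundaries: 0.19 weak; 0.2 moderate (assigned upward); 0.6 strong
  expect_equal(effect_size_label(c(0.19, 0.2, -0.35, 0.6, 0.5)),
               c("weak", "moderate", "moderate", "strong", "moderate"))
})

test_that("Holm adjustment matches the closed form and stats::p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(rep(0.05, 3)), rep(0.15, 3))
  set.seed(4)
  for (r in 1:10) {
    p <- stats::runif(sample(2:8, 1))
    expect_equal(holm_adjust(p), stats::p.adjust(p, "holm"))
    expect_true(all(holm_adjust(p) >= p))
  }
})

test_that("follow-up paired t-tests isolate the pressure effect within feedback levels", {
  truth0 <- selfreport_truth(beta_pressure_on_cof = 0,
                             beta_feedback_on_cof = 0,
                             beta_interaction_on_cof = 0)
  d <- probe_design(sprintf("P%02d", 1:40), seed = 31)
  d <- generate_selfreports(d, truth0, seed = 31)
  # inject a pressure effect only under high feedback
  boost <- d$feedback == "high" & d$pressure == "high"
  d$cof <- pmin(6, d$cof + 1.5 * boost)
  res <- holm_followups(d, "cof", list(
    list(factor = "pressure", within = c(feedback = "low")),
    list(factor = "pressure", within = c(feedback = "high"))))
  expect_equal(nrow(res), 2L)
  expect_lt(res$p_adjusted[2], 1e-6)
  expect_gt(res$p_adjusted[1] / res$p_adjusted[2], 1e3)
  expect_true(all(res$p_adjusted >= res$p_raw))
})

test_that("winsorization before fitting leaves clean data unchanged", {
  d <- make_probes(seed = 41)
  grp <- paste(d$pressure, d$feedback)
  w <- winsorize(d$pof, grp)
  # generator output is bounded; at most a handful of values touch 3 SD
  expect_gt(mean(w == d$pof), 0.99)
  fit1 <- fit_condition_model(d, "pof")
  d$pof <- w
  fit2 <- fit_condition_model(d, "pof")
  expect_equal(coef(fit1)[["feedback01"]], coef(fit2)[["feedback01"]],
               tolerance = 0.05)
})
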