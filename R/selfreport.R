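# Probe self-reports: probability-of-failure (POF) and cost-of-failure (COF)
# appraisals on 0-6 Likert scales and an anxiety thermometer on 0-10. Reports
# are generated from participant-random-intercept linear models whose fixed
# effects default to the coefficients the analysis recipes are designed to
# recover, so fitted models can be scored against known truth.

#' Generative truth for probe self-reports
#'
#' Fixed-effect defaults are the effect sizes the package's analysis recipes
#' target: feedback raises POF, the pressure-by-feedback interaction raises
#' COF, and POF and COF (plus a small interaction) raise anxiety. Intercepts
#' and variance components are generator choices made so that every
#' condition-cell mean sits at least 3 combined SDs from both scale bounds
#' (boundary clipping below ~0.3%, so the clipped linear model is recovered
#' without visible censoring bias) while keeping realistic intraclass
#' correlations (about 0.5 for POF, higher for COF).
#'
#' @param pof_intercept,cof_intercept,anx_intercept Scale-unit intercepts.
#' @param beta_feedback_on_pof,beta_pressure_on_pof,beta_interaction_on_pof
#'   Condition effects on POF (0/1 indicator coding, low/low reference).
#' @param beta_pressure_on_cof,beta_feedback_on_cof,beta_interaction_on_cof
#'   Condition effects on COF.
#' @param beta_pof_on_anx,beta_cof_on_anx,beta_pofxcof_on_anx Appraisal
#'   effects on anxiety.
#' @param pof_ranef_sd,cof_ranef_sd,anx_ranef_sd Participant random-intercept
#'   SDs.
#' @param pof_resid_sd,cof_resid_sd,anx_resid_sd Residual SDs.
#' @return A validated list of class \code{"ivr_selfreport_truth"}.
#' @export
selfreport_truth <- function(pof_intercept = 3.0,
                             cof_intercept = 2.5,
                             anx_intercept = 2.5,
                             beta_feedback_on_pof = 0.46,
                             beta_pressure_on_pof = -0.01,
                             beta_interaction_on_pof = 0.06,
                             beta_pressure_on_cof = -0.12,
                             beta_feedback_on_cof = 0.07,
                             beta_interaction_on_cof = 0.43,
                             beta_pof_on_anx = 0.18,
                             beta_cof_on_anx = 0.29,
                             beta_pofxcof_on_anx = 0.02,
                             pof_ranef_sd = 0.55, pof_resid_sd = 0.55,
                             cof_ranef_sd = 0.65, cof_resid_sd = 0.4,
                             anx_ranef_sd = 0.8, anx_resid_sd = 0.6) {
  truth <- list(pof_intercept = pof_intercept, cof_intercept = cof_intercept,
                anx_intercept = anx_intercept,
                beta_feedback_on_pof = beta_feedback_on_pof,
                beta_pressure_on_pof = beta_pressure_on_pof,
                beta_interaction_on_pof = beta_interaction_on_pof,
                beta_pressure_on_cof = beta_pressure_on_cof,
                beta_feedback_on_cof = beta_feedback_on_cof,
                beta_interaction_on_cof = beta_interaction_on_cof,
                beta_pof_on_anx = beta_pof_on_anx,
                beta_cof_on_anx = beta_cof_on_anx,
                beta_pofxcof_on_anx = beta_pofxcof_on_anx,
                pof_ranef_sd = pof_ranef_sd, pof_resid_sd = pof_resid_sd,
                cof_ranef_sd = cof_ranef_sd, cof_resid_sd = cof_resid_sd,
                anx_ranef_sd = anx_ranef_sd, anx_resid_sd = anx_resid_sd)
  sds <- truth[grepl("_sd$", names(truth))]
  if (any(unlist(sds) < 0))
    stop("selfreport truth: all SDs must be >= 0", call. = FALSE)
  class(truth) <- "ivr_selfreport_truth"
  truth
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate probe self-reports for a set of participants
#'
#' Expects a probe design with one row per probe (participant, pressure and
#' feedback condition indicators, trial index, feedback call); typically all
#' 6 probes x 4 blocks per participant. POF and COF are drawn from
#' condition-effect models with participant random intercepts and Gaussian
#' noise, anxiety from POF, COF and their product, and all three are clipped
#' to their scales (POF/COF to [0,6], anxiety to [0,10]).
#'
#' @param design data.frame with columns \code{participant},
#'   \code{pressure} ("low"/"high"), \code{feedback} ("low"/"high"); other
#'   columns are carried through.
#' @param truth A \code{\link{selfreport_truth}}.
#' @param seed Optional integer seed.
#' @return The design with columns \code{pof}, \code{cof}, \code{anxiety}
#'   appended.
#' @export
generate_selfreports <- function(design, truth = selfreport_truth(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("participant", "pressure", "feedback") %in% names(design)))
  ids <- unique(design$participant)
  press <- as.numeric(design$pressure == "high")
  feed <- as.numeric(design$feedback == "high")
  re <- function(sd) {
    u <- stats::rnorm(length(ids), 0, sd)
    u[match(design$participant, ids)]
  }
  n <- nrow(design)
  pof <- truth$pof_intercept +
    truth$beta_feedback_on_pof * feed +
    truth$beta_pressure_on_pof * press +
    truth$beta_interaction_on_pof * press * feed +
    re(truth$pof_ranef_sd) + stats::rnorm(n, 0, truth$pof_resid_sd)
  cof <- truth$cof_intercept +
    truth$beta_pressure_on_cof * press +
    truth$beta_feedback_on_cof * feed +
    truth$beta_interaction_on_cof * press * feed +
    re(truth$cof_ranef_sd) + stats::rnorm(n, 0, truth$cof_resid_sd)
  pof <- clip(pof, 0, 6)
  cof <- clip(cof, 0, 6)
  anx <- truth$anx_intercept +
    truth$beta_pof_on_anx * pof +
    truth$beta_cof_on_anx * cof +
    truth$beta_pofxcof_on_anx * pof * cof +
    re(truth$anx_ranef_sd) + stats::rnorm(n, 0, truth$anx_resid_sd)
  design$pof <- pof
  design$cof <- cof
  design$anxiety <- clip(anx, 0, 10)
  design
}

#' Build the probe design grid for a set of participants
#'
#' One row per probe: 4 blocks (2x2 pressure by feedback, order given by
#' \code{block_order}) with the probe trials of each block's schedule.
#'
#' @param participants Character or integer participant ids.
#' @param schedules Named list of \code{\link{build_feedback_schedule}}
#'   results, one per feedback level, or a function
#'   \code{(feedback, seed) -> schedule}.
#' @param seed Base seed; per-participant schedule seeds derive from it.
#' @return data.frame with participant, block, pressure, feedback, trial and
#'   feedback_call columns.
#' @export
probe_design <- function(participants, schedules = NULL, seed = 1L) {
  blocks <- expand.grid(pressure = c("low", "high"),
                        feedback = c("low", "high"),
                        stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_along(participants)) {
    for (b in seq_len(nrow(blocks))) {
      fb <- blocks$feedback[b]
      sch <- if (is.list(schedules) && !is.null(schedules[[fb]])) {
        schedules[[fb]]
      } else {
        build_feedback_schedule(fb, seed = derive_seed(seed, (i - 1L) * 4L + b))
      }
      out[[length(out) + 1L]] <- data.frame(
        participant = participants[i],
        block = b,
        pressure = blocks$pressure[b],
        feedback = fb,
        trial = sch$probe_trials,
        feedback_call = sch$feedback_calls[sch$probe_trials],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# small deterministic seed derivation kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}
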