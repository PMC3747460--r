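#' Effect-size constants for the simulation models
#'
#' The data-generating process uses four log-odds-ratio / log-hazard-ratio
#' magnitudes denoting weak, moderate, strong, and very strong covariate
#' effects: log(1.25), log(1.5), log(1.75), and log(2).
#'
#' @return Named numeric vector with elements `weak`, `moderate`, `strong`,
#'   `very_strong`.
#' @export
effect_sizes <- function() {
  c(weak = log(1.25), moderate = log(1.5), strong = log(1.75),
    very_strong = log(2))
}

# Fixed slope vectors. Treatment selection depends on X1..X7; the outcome
# hazard depends on X4..X10, so X4..X7 confound, X1..X3 are instruments and
# X8..X10 affect only the outcome.
treatment_slopes <- function() {
  e <- effect_sizes()
  unname(e[c("weak", "moderate", "strong", "weak", "moderate", "strong",
             "very_strong")])
}

outcome_slopes <- function() {
  e <- effect_sizes()
  unname(e[c("weak", "moderate", "strong", "very_strong", "weak", "moderate",
             "strong")])
}

#' Treatment-selection model
#'
#' Logistic model for treatment assignment: `logit(p) = intercept + a' x[1:7]`
#' with fixed slopes (weak, moderate, strong, weak, moderate, strong, very
#' strong) on covariates X1..X7. Only the intercept is free; it controls the
#' marginal treatment prevalence.
#'
#' @param intercept Intercept on the log-odds scale. Usually produced by
#'   [calibrate_treatment_intercept()].
#' @param slopes Slope coefficients on X1..X7. The default is the study's
#'   fixed vector; overriding it (e.g. with zeros) supports diagnostic
#'   designs without treatment-selection effects.
#' @return An object of class `treatment_model`.
#' @seealso [calibrate_treatment_intercept()], [assign_treatment()]
#' @export
treatment_model <- function(intercept, slopes = treatment_slopes()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            !is.na(intercept), length(slopes) == 7L)
  structure(list(intercept = intercept, slopes = as.numeric(slopes)),
            class = "treatment_model")
}

#' Weibull proportional-hazards outcome model
#'
#' Event times follow a Weibull proportional-hazards model with linear
#' predictor `LP = beta_treat * z + b' x[4:10]`, baseline scale `lambda` and
#' shape `eta`. The covariate coefficients on X4..X10 are fixed at (weak,
#' moderate, strong, very strong, weak, moderate, strong); only the
#' conditional treatment effect `beta_treat` is free.
#'
#' @param beta_treat Conditional log-hazard ratio for treatment.
#' @param lambda Baseline Weibull scale parameter (> 0). Default 0.00002.
#' @param eta Weibull shape parameter (> 0). Default 2.
#' @param slopes Covariate coefficients on X4..X10. The default is the
#'   study's fixed vector; setting them to zero gives a collapsible design
#'   in which marginal and conditional hazard ratios coincide.
#' @return An object of class `outcome_model`.
#' @seealso [generate_event_times()], [calibrate_conditional_beta()]
#' @export
outcome_model <- function(beta_treat, lambda = 0.00002, eta = 2,
                          slopes = outcome_slopes()) {
  stopifnot(is.numeric(beta_treat), length(beta_treat) == 1L,
            !is.na(beta_treat), length(slopes) == 7L)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("`lambda` must be a single positive number")
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0)
    stop("`eta` must be a single positive number")
  structure(list(beta_treat = beta_treat, slopes = as.numeric(slopes),
                 lambda = lambda, eta = eta),
            class = "outcome_model")
}

#' Simulation scenario configuration
#'
#' Bundles the design factors of one simulation scenario: cohort size,
#' treatment prevalence, target marginal hazard ratio, estimand framing
#' (ATE: marginal effect in the whole population; ATT: marginal effect in
#' the treated), replicate count and master seed.
#'
#' @param n_subjects Number of subjects per simulated cohort (default 10000).
#' @param prop_treated Target treatment prevalence, strictly in (0, 1).
#' @param target_marginal_hr Target marginal hazard ratio (> 0).
#' @param estimand `"ATE"` or `"ATT"`.
#' @param n_reps Number of Monte Carlo replicates (>= 1).
#' @param seed Master seed (integer) controlling all randomness in the
#'   scenario.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_subjects = 10000, prop_treated,
                            target_marginal_hr = 1,
                            estimand = c("ATE", "ATT"),
                            n_reps = 1, seed = 1L) {
  estimand <- match.arg(estimand)
  if (!is.numeric(prop_treated) || length(prop_treated) != 1L ||
      prop_treated <= 0 || prop_treated >= 1)
    stop("`prop_treated` must lie strictly between 0 and 1")
  if (!is.numeric(target_marginal_hr) || target_marginal_hr <= 0)
    stop("`target_marginal_hr` must be positive")
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("`n_reps` must be at least 1")
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be at least 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 prop_treated = prop_treated,
                 target_marginal_hr = target_marginal_hr,
                 estimand = estimand,
                 n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: n=%d, %.0f%% treated, target marginal HR %.3g (%s), %d reps, seed %d\n",
    x$n_subjects, 100 * x$prop_treated, x$target_marginal_hr, x$estimand,
    x$n_reps, x$seed))
  invisible(x)
}
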