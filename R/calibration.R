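# Marginal vs conditional hazard ratios. The Weibull data-generating process
# takes a conditional log-hazard ratio beta_treat; because hazard ratios are
# non-collapsible, the induced marginal (population-average) hazard ratio is
# closer to the null whenever covariates affect the outcome. These functions
# measure the marginal effect by potential-outcomes simulation and invert the
# (monotone) map beta_treat -> marginal log-HR by bisection.

#' Estimate the marginal log-hazard ratio induced by a conditional effect
#'
#' For each Monte Carlo replicate, a cohort is simulated and each subject
#' receives two potential event times: one with treatment forced off and one
#' with treatment forced on (same covariates, independent uniform draws per
#' arm). The 2n records are stacked with a treatment-arm indicator and a
#' univariate Cox model is fitted; under the ATT framing the stacked sample
#' is first restricted to subjects whose realized treatment assignment was
#' treated. The mean coefficient across replicates estimates the marginal
#' log-hazard ratio.
#'
#' @param beta_treat Conditional log-hazard ratio in the outcome model.
#' @param scenario A [scenario_config()] (supplies cohort size and treatment
#'   prevalence).
#' @param n_mc_reps Number of Monte Carlo replicates (default 1000).
#' @param estimand `"ATE"` (whole population) or `"ATT"` (treated only);
#'   defaults to the scenario's framing.
#' @param seed Seed for the replicate substreams (default: scenario seed).
#' @param intercept Optional pre-calibrated treatment-model intercept.
#' @param outcome_cov_slopes Covariate coefficients of the outcome model
#'   (default: the study's fixed vector; zeros give a collapsible design).
#' @return List with `estimate` (mean log-HR), `mc_se` (Monte Carlo standard
#'   error of the mean), `n_used`, `coefs`.
#' @export
estimate_marginal_loghr <- function(beta_treat, scenario, n_mc_reps = 1000,
                                    estimand = scenario$estimand,
                                    seed = scenario$seed,
                                    intercept = NULL,
                                    outcome_cov_slopes = outcome_slopes()) {
  stopifnot(inherits(scenario, "scenario_config"), n_mc_reps >= 1)
  estimand <- match.arg(estimand, c("ATE", "ATT"))
  if (is.null(intercept))
    intercept <- calibrate_treatment_intercept(scenario$prop_treated)
  tmodel <- treatment_model(intercept)
  omodel <- outcome_model(beta_treat, slopes = outcome_cov_slopes)
  n <- scenario$n_subjects
  streams <- make_rng_streams(seed, n_mc_reps)
  coefs <- vapply(seq_len(n_mc_reps), function(i) {
    with_rng_stream(streams[[i]], {
      X <- generate_covariates(n)
      Z <- assign_treatment(X, tmodel)
      t0 <- generate_event_times(X, rep(0L, n), omodel)
      t1 <- generate_event_times(X, rep(1L, n), omodel)
      keep <- if (estimand == "ATT") Z == 1L else rep(TRUE, n)
      dat <- data.frame(time = c(t0[keep], t1[keep]),
                        arm = rep(c(0L, 1L), each = sum(keep)))
      tryCatch(
        unname(stats::coef(survival::coxph(
          survival::Surv(time) ~ arm, data = dat, ties = "efron"))),
        error = function(e) NA_real_)
    })
  }, numeric(1))
  ok <- is.finite(coefs)
  if (mean(!ok) > 0.05)
    stop("more than 5% of marginalization replicates failed")
  if (any(!ok))
    warning(sum(!ok), " marginalization replicate(s) failed and were skipped")
  est <- mean(coefs[ok])
  list(estimate = est,
       mc_se = stats::sd(coefs[ok]) / sqrt(sum(ok)),
       n_used = sum(ok), coefs = coefs[ok])
}

#' Calibrate the conditional effect to a target marginal hazard ratio
#'
#' Bisection on `beta_treat`, exploiting the monotonicity of the induced
#' marginal log-hazard ratio in the conditional one. Each candidate is
#' evaluated with [estimate_marginal_loghr()]; iteration stops when the
#' achieved marginal log-HR is within `tol` of `log(target_marginal_hr)`.
#' The initial bracket `log(target) +/- (0.5 |log(target)| + 0.1)` is widened
#' adaptively if it does not straddle the root; expansion beyond +/- 5 on the
#' log scale aborts (a misconfigured model).
#'
#' @param target_marginal_hr Target marginal hazard ratio (> 0).
#' @param estimand `"ATE"` or `"ATT"`.
#' @param scenario A [scenario_config()].
#' @param tol Convergence tolerance on the log-HR scale (default 0.005).
#' @param n_mc_reps Replicates per bisection evaluation (default 1000; the
#'   reference fidelity. Smaller values give a fast desk-scale mode).
#' @param seed Master seed; each bisection evaluation uses its own
#'   substream.
#' @param max_iter Maximum bisection iterations.
#' @param outcome_cov_slopes Covariate coefficients of the outcome model
#'   (default: the study's fixed vector).
#' @return Object of class `ps_calibration`: list with `target_hr`,
#'   `estimand`, `beta_treat`, `achieved` (marginal log-HR at convergence),
#'   `mc_se`, `iterations`, `trace` (per-iteration bracket and estimates).
#' @export
calibrate_conditional_beta <- function(target_marginal_hr,
                                       estimand = c("ATE", "ATT"),
                                       scenario,
                                       tol = 0.005, n_mc_reps = 1000,
                                       seed = scenario$seed,
                                       max_iter = 60L,
                                       outcome_cov_slopes = outcome_slopes()) {
  estimand <- match.arg(estimand)
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.numeric(target_marginal_hr) || target_marginal_hr <= 0)
    stop("`target_marginal_hr` must be positive")
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive")
  lt <- log(target_marginal_hr)
  intercept <- calibrate_treatment_intercept(scenario$prop_treated)
  eval_seed <- function(k) (as.integer(seed) + 7919L * k) %% 2147483647L
  k <- 0L
  f <- function(beta) {
    k <<- k + 1L
    r <- estimate_marginal_loghr(beta, scenario, n_mc_reps = n_mc_reps,
                                 estimand = estimand, seed = eval_seed(k),
                                 intercept = intercept,
                                 outcome_cov_slopes = outcome_cov_slopes)
    r
  }
  lo <- lt - 0.5 * abs(lt) - 0.1
  hi <- lt + 0.5 * abs(lt) + 0.1
  trace <- list()
  rec <- function(iter, lo, hi, beta, r) {
    trace[[length(trace) + 1L]] <<- data.frame(
      iter = iter, lo = lo, hi = hi, beta = beta,
      estimate = r$estimate, mc_se = r$mc_se)
  }
  flo <- f(lo); rec(0L, lo, hi, lo, flo)
  fhi <- f(hi); rec(0L, lo, hi, hi, fhi)
  # widen until the bracket straddles the target
  while (flo$estimate > lt || fhi$estimate < lt) {
    if (flo$estimate > lt) {
      lo <- lo - (0.5 * abs(lt) + 0.1)
      if (lo < -5) stop("bracket expansion exceeded -5 on the log-HR scale")
      flo <- f(lo); rec(0L, lo, hi, lo, flo)
    }
    if (fhi$estimate < lt) {
      hi <- hi + (0.5 * abs(lt) + 0.1)
      if (hi > 5) stop("bracket expansion exceeded +5 on the log-HR scale")
      fhi <- f(hi); rec(0L, lo, hi, hi, fhi)
    }
  }
  beta <- NA_real_; achieved <- NA_real_; mc_se <- NA_real_
  iter <- 0L
  repeat {
    iter <- iter + 1L
    beta <- (lo + hi) / 2
    r <- f(beta)
    rec(iter, lo, hi, beta, r)
    achieved <- r$estimate; mc_se <- r$mc_se
    if (abs(achieved - lt) <= tol) break
    if (iter >= max_iter) {
      warning("bisection reached max_iter without meeting tol; ",
              "returning best midpoint")
      break
    }
    if (achieved < lt) lo <- beta else hi <- beta
  }
  structure(list(target_hr = target_marginal_hr, estimand = estimand,
                 prop_treated = scenario$prop_treated,
                 beta_treat = beta, achieved = achieved, mc_se = mc_se,
                 iterations = iter, n_mc_reps = n_mc_reps,
                 trace = do.call(rbind, trace)),
            class = "ps_calibration")
}

#' @export
print.ps_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration: target marginal HR %.3g (%s, %.0f%% treated)\n  beta_treat = %.5f (conditional HR %.4f), achieved marginal log-HR %.5f (MC SE %.4g), %d bisection iterations\n",
    x$target_hr, x$estimand, 100 * x$prop_treated, x$beta_treat,
    exp(x$beta_treat), x$achieved, x$mc_se, x$iterations))
  invisible(x)
}

#' Calibration cache
#'
#' Calibrated conditional effects are expensive to recompute, so they can be
#' stored in (and looked up from) a JSON table keyed by target hazard ratio,
#' estimand, and treatment prevalence. The package ships a table covering
#' the 21-scenario grid for both estimands, computed with
#' `scripts/build_calibrations.R`.
#'
#' @param path JSON file path. `default_calibrations()` reads the shipped
#'   table.
#' @return A data frame with columns `target_hr`, `estimand`,
#'   `prop_treated`, `beta_treat`, `achieved`, `mc_se`, `n_mc_reps`.
#' @export
load_calibrations <- function(path) {
  out <- jsonlite::fromJSON(path)
  as.data.frame(out)
}

#' @rdname load_calibrations
#' @export
default_calibrations <- function() {
  load_calibrations(system.file("extdata", "calibrations.json",
                                package = "pshazard", mustWork = TRUE))
}

#' @rdname load_calibrations
#' @param calibrations Data frame from [load_calibrations()].
#' @param target_hr,estimand,prop_treated Scenario key.
#' @return `lookup_calibration`: the calibrated `beta_treat`, or `NA` if the
#'   key is absent.
#' @export
lookup_calibration <- function(calibrations, target_hr, estimand,
                               prop_treated) {
  hit <- abs(calibrations$target_hr - target_hr) < 1e-9 &
    calibrations$estimand == estimand &
    abs(calibrations$prop_treated - prop_treated) < 1e-9
  if (!any(hit)) return(NA_real_)
  calibrations$beta_treat[which(hit)[1]]
}

#' @rdname load_calibrations
#' @param results List of `ps_calibration` objects.
#' @export
save_calibrations <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(x) data.frame(
    target_hr = x$target_hr, estimand = x$estimand,
    prop_treated = x$prop_treated, beta_treat = x$beta_treat,
    achieved = x$achieved, mc_se = x$mc_se, n_mc_reps = x$n_mc_reps)))
  rownames(df) <- NULL
  jsonlite::write_json(df, path, digits = NA, pretty = TRUE)
  invisible(path)
}
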