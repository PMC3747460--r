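#' Aggregate per-replicate estimates into performance metrics
#'
#' Given one method's effect estimates across simulation replicates and the
#' true marginal log-hazard ratio `theta`, computes: mean estimate, bias,
#' relative bias (100 * bias / theta; omitted when theta = 0), MSE
#' (mean squared deviation from theta), mean estimated SE, empirical SD of
#' the estimates, their ratio (1 indicates correctly calibrated variance
#' estimation), empirical coverage of the 95% confidence intervals, mean CI
#' length on the hazard-ratio scale (exponentiated endpoints; the log-scale
#' length is also recorded), and the Monte Carlo SE of the mean estimate.
#' Non-converged replicates are dropped.
#'
#' @param estimates Data frame of effect estimates for a single method
#'   (columns `loghr`, `se`, `ci_low`, `ci_high`, `converged`).
#' @param theta True marginal log-hazard ratio.
#' @return One-row data frame of class `method_performance`.
#' @export
compute_metrics <- function(estimates, theta) {
  est <- estimates[is.finite(estimates$loghr) & estimates$converged, ,
                   drop = FALSE]
  if (nrow(est) == 0L) stop("no converged estimates to aggregate")
  if (nrow(est) < 2L) stop("need at least 2 converged estimates")
  th <- est$loghr
  m <- mean(th)
  bias <- m - theta
  sd_th <- stats::sd(th)
  out <- data.frame(
    method = if ("method" %in% names(est)) est$method[1] else NA_character_,
    n_reps = nrow(est),
    mean_loghr = m,
    bias = bias,
    rel_bias_pct = if (theta == 0) NA_real_ else 100 * bias / theta,
    mse = mean((th - theta)^2),
    mean_se = mean(est$se),
    sd_loghr = sd_th,
    se_sd_ratio = mean(est$se) / sd_th,
    coverage = mean(est$ci_low <= theta & theta <= est$ci_high),
    ci_length_hr = mean(exp(est$ci_high) - exp(est$ci_low)),
    ci_length_log = mean(est$ci_high - est$ci_low),
    mc_se_mean = sd_th / sqrt(nrow(est)),
    stringsAsFactors = FALSE)
  class(out) <- c("method_performance", "data.frame")
  out
}

#' Significance bounds for empirical coverage of a 95% interval
#'
#' Normal-approximation bounds outside of which an empirical coverage rate
#' differs significantly from the nominal level:
#' `level +/- 1.96 * sqrt(level * (1 - level) / n_reps)`.
#'
#' @param n_reps Number of simulation replicates (default 10000).
#' @param level Nominal coverage (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
coverage_significance_bounds <- function(n_reps = 10000, level = 0.95) {
  half <- 1.96 * sqrt(level * (1 - level) / n_reps)
  c(lower = level - half, upper = level + half)
}

#' Run one simulation scenario
#'
#' For each replicate: simulate a cohort under the scenario's treatment
#' model (prevalence-calibrated intercept) and outcome model (conditional
#' effect `beta_treat`), fit the propensity score on X4..X10, build the
#' requested conditioning designs, run the requested estimators, and
#' aggregate the per-replicate estimates with [compute_metrics()] against
#' the scenario's true marginal log-hazard ratio.
#'
#' `beta_treat` is resolved in order from: the explicit argument, a
#' `calibrations` table lookup, or a fresh [calibrate_conditional_beta()]
#' run at `calib_reps` replicates per bisection evaluation.
#'
#' @param scenario A [scenario_config()].
#' @param methods Estimators to run (default all nine).
#' @param beta_treat Conditional log-HR inducing the scenario's target
#'   marginal HR (optional).
#' @param calibrations Optional calibration table (see
#'   [load_calibrations()]).
#' @param calib_reps Replicates per bisection evaluation when calibrating in
#'   place.
#' @param mc.cores Number of worker processes for replicates (forked;
#'   results are identical for any worker count).
#' @param keep_estimates Keep the per-replicate estimates in the result.
#' @return Object of class `scenario_result`: list with `config`,
#'   `beta_treat`, `theta` (true marginal log-HR), `performance` (one row
#'   per method), `avg_pairs`, `frac_treated_matched`, `n_failed`, and
#'   optionally `estimates`.
#' @export
run_scenario <- function(scenario, methods = estimator_labels(),
                         beta_treat = NULL, calibrations = NULL,
                         calib_reps = 200, mc.cores = 1L,
                         keep_estimates = FALSE) {
  stopifnot(inherits(scenario, "scenario_config"))
  theta <- log(scenario$target_marginal_hr)
  if (is.null(beta_treat) && !is.null(calibrations))
    beta_treat <- lookup_calibration(calibrations,
                                     scenario$target_marginal_hr,
                                     scenario$estimand,
                                     scenario$prop_treated)
  if (is.null(beta_treat) || is.na(beta_treat)) {
    cal <- calibrate_conditional_beta(scenario$target_marginal_hr,
                                      scenario$estimand, scenario,
                                      n_mc_reps = calib_reps)
    beta_treat <- cal$beta_treat
  }
  intercept <- calibrate_treatment_intercept(scenario$prop_treated)
  tmodel <- treatment_model(intercept)
  omodel <- outcome_model(beta_treat)
  streams <- make_rng_streams(scenario$seed, scenario$n_reps)
  one_rep <- function(i) {
    with_rng_stream(streams[[i]], {
      cohort <- generate_cohort(scenario$n_subjects, tmodel, omodel)
      tryCatch({
        est <- estimate_all(cohort, methods)
        est$rep <- i
        list(est = est, n_pairs = attr(est, "n_pairs"),
             n_treated = attr(est, "n_treated"))
      }, error = function(e) list(error = conditionMessage(e)))
    })
  }
  reps <- if (mc.cores > 1L)
    parallel::mclapply(seq_len(scenario$n_reps), one_rep,
                       mc.cores = mc.cores)
  else
    lapply(seq_len(scenario$n_reps), one_rep)
  failed <- vapply(reps, function(r) !is.null(r$error), logical(1))
  if (mean(failed) > 0.05)
    stop("more than 5% of replicates failed; first error: ",
         reps[[which(failed)[1]]]$error)
  ok <- reps[!failed]
  estimates <- do.call(rbind, lapply(ok, `[[`, "est"))
  perf <- do.call(rbind, lapply(split(estimates, estimates$method),
                                compute_metrics, theta = theta))
  perf <- perf[match(methods, perf$method), , drop = FALSE]
  rownames(perf) <- NULL
  n_pairs <- vapply(ok, `[[`, numeric(1), "n_pairs")
  n_treated <- vapply(ok, `[[`, numeric(1), "n_treated")
  res <- list(config = scenario, beta_treat = beta_treat, theta = theta,
              performance = perf,
              avg_pairs = mean(n_pairs),
              frac_treated_matched = if (all(is.na(n_pairs))) NA_real_
                else mean(n_pairs / n_treated),
              n_failed = sum(failed))
  if (keep_estimates) res$estimates <- estimates
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$config)
  cat(sprintf("beta_treat = %.5f, true marginal log-HR = %.5f\n",
              x$beta_treat, x$theta))
  if (!is.na(x$avg_pairs))
    cat(sprintf("avg matched pairs %.1f (%.1f%% of treated)\n",
                x$avg_pairs, 100 * x$frac_treated_matched))
  print(as.data.frame(x$performance), digits = 4)
  invisible(x)
}

#' Run the factorial scenario grid
#'
#' Executes the cross-product of treatment prevalences and target marginal
#' hazard ratios under one estimand framing (the study design is 3
#' prevalences x 7 hazard ratios = 21 scenarios) and collects tidy
#' performance tables.
#'
#' @param prevalences Treatment prevalences (non-empty).
#' @param marginal_hrs Target marginal hazard ratios (non-empty).
#' @param estimand `"ATE"` or `"ATT"`.
#' @param n_subjects Subjects per cohort.
#' @param n_reps Replicates per scenario.
#' @param seed Master seed; per-scenario seeds are derived from it.
#' @param methods Estimators to run.
#' @param calibrations Optional calibration table.
#' @param out_dir Optional output directory: writes `metrics.csv` (one row
#'   per scenario x method) and `manifest.json` (seeds and calibrated
#'   effects).
#' @param mc.cores Worker processes per scenario.
#' @return Object of class `grid_result`: list with `scenarios` (list of
#'   `scenario_result`) and `metrics` (tidy data frame).
#' @export
run_grid <- function(prevalences, marginal_hrs, estimand = c("ATE", "ATT"),
                     n_subjects = 10000, n_reps = 100, seed = 1L,
                     methods = estimator_labels(), calibrations = NULL,
                     out_dir = NULL, mc.cores = 1L) {
  estimand <- match.arg(estimand)
  if (length(prevalences) == 0L) stop("`prevalences` must be non-empty")
  if (length(marginal_hrs) == 0L) stop("`marginal_hrs` must be non-empty")
  grid <- expand.grid(prop_treated = prevalences, target_hr = marginal_hrs,
                      KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    sc_seed <- (as.integer(seed) * 1009L + k) %% 2147483647L
    sc <- scenario_config(n_subjects = n_subjects,
                          prop_treated = grid$prop_treated[k],
                          target_marginal_hr = grid$target_hr[k],
                          estimand = estimand, n_reps = n_reps,
                          seed = sc_seed)
    res <- run_scenario(sc, methods = methods, calibrations = calibrations,
                        mc.cores = mc.cores)
    results[[k]] <- res
    perf <- as.data.frame(res$performance)
    perf$prop_treated <- sc$prop_treated
    perf$target_hr <- sc$target_marginal_hr
    perf$estimand <- estimand
    perf$scenario <- k
    rows[[k]] <- perf
  }
  metrics <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    manifest <- list(
      seed = as.integer(seed), estimand = estimand,
      n_subjects = as.integer(n_subjects), n_reps = as.integer(n_reps),
      scenarios = data.frame(
        scenario = seq_len(nrow(grid)),
        prop_treated = grid$prop_treated,
        target_hr = grid$target_hr,
        seed = vapply(results, function(r) r$config$seed, integer(1)),
        beta_treat = vapply(results, `[[`, numeric(1), "beta_treat")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(scenarios = results, metrics = metrics),
            class = "grid_result")
}

#' Average matched-pair yield of the matching design
#'
#' Repeatedly simulates cohorts under a given treatment prevalence (the
#' outcome model does not influence matching), fits the propensity score on
#' X4..X10, forms the 1:1 caliper-matched sample, and reports the average
#' number of pairs and the average fraction of treated subjects matched.
#'
#' @param prop_treated Treatment prevalence.
#' @param n_subjects Cohort size (default 10000).
#' @param n_reps Number of simulated cohorts (default 100).
#' @param seed Master seed.
#' @param caliper_sd_multiple Caliper width multiple (default 0.2).
#' @return List with `avg_pairs`, `frac_treated_matched`, `n_reps`.
#' @export
matching_yield <- function(prop_treated, n_subjects = 10000, n_reps = 100,
                           seed = 1L, caliper_sd_multiple = 0.2) {
  intercept <- calibrate_treatment_intercept(prop_treated)
  tmodel <- treatment_model(intercept)
  streams <- make_rng_streams(seed, n_reps)
  pairs <- treated <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    r <- with_rng_stream(streams[[i]], {
      X <- generate_covariates(n_subjects)
      Z <- assign_treatment(X, tmodel)
      ps <- fit_propensity_model(X, Z)
      m <- greedy_caliper_match(ps$logit_ps, Z, caliper_sd_multiple)
      c(nrow(m$pairs), sum(Z))
    })
    pairs[i] <- r[1]
    treated[i] <- r[2]
  }
  list(avg_pairs = mean(pairs),
       frac_treated_matched = mean(pairs / treated),
       n_reps = n_reps)
}
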