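#' Generate baseline covariates
#'
#' Draws an `n x 10` matrix of independent standard-normal covariates
#' X1..X10. Columns X1..X3 affect only treatment selection, X4..X7 affect
#' both treatment and outcome (confounders), X8..X10 affect only the
#' outcome.
#'
#' Consumes the current RNG state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param n Number of subjects (>= 0).
#' @return Numeric matrix with `n` rows and 10 columns named `x1`..`x10`.
#' @export
generate_covariates <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("`n` must be a non-negative count")
  n <- as.integer(n)
  X <- matrix(stats::rnorm(n * 10L), nrow = n, ncol = 10L)
  colnames(X) <- paste0("x", 1:10)
  X
}

#' Calibrate the treatment-model intercept to a target prevalence
#'
#' Finds the intercept `a0` such that the expected treatment prevalence
#' `E[expit(a0 + LP)]` equals `prop_treated`, where the linear predictor
#' `LP` over independent standard-normal covariates is exactly
#' `Normal(0, sigma^2)` with `sigma^2` the sum of squared slopes. The
#' expectation is computed by one-dimensional Gaussian quadrature
#' (`stats::integrate`) and inverted with a bracketing root finder to an
#' absolute tolerance of 1e-6 on the probability scale.
#'
#' The prevalence is matched in expectation; the realized per-sample
#' prevalence is then binomial.
#'
#' @param prop_treated Target prevalence, strictly in (0, 1).
#' @param slopes Slope coefficients of the treatment model (default: the
#'   fixed simulation slopes on X1..X7).
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_treatment_intercept <- function(prop_treated,
                                          slopes = treatment_slopes()) {
  if (!is.numeric(prop_treated) || length(prop_treated) != 1L ||
      is.na(prop_treated) || prop_treated <= 0 || prop_treated >= 1)
    stop("`prop_treated` must lie strictly between 0 and 1")
  sigma <- sqrt(sum(slopes^2))
  prev <- function(a0) {
    if (sigma == 0) return(stats::plogis(a0))
    stats::integrate(function(z) stats::plogis(a0 + sigma * z) *
                       stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-12)$value
  }
  # Marginal prevalence is monotone in a0; a wide fixed bracket suffices.
  root <- stats::uniroot(function(a0) prev(a0) - prop_treated,
                         interval = c(-40, 40), tol = 1e-12)
  a0 <- root$root
  if (abs(prev(a0) - prop_treated) > 1e-6)
    stop(sprintf(
      "intercept calibration did not converge: residual %.3g at a0 = %.6f",
      prev(a0) - prop_treated, a0))
  a0
}

#' Assign treatment status
#'
#' Draws `Z_i ~ Bernoulli(expit(a0 + a' x_i[1:7]))`. Only covariates X1..X7
#' enter the treatment model.
#'
#' @param X Covariate matrix with 10 columns (from [generate_covariates()]).
#' @param model A [treatment_model()].
#' @return Integer vector of 0/1 treatment indicators.
#' @export
assign_treatment <- function(X, model) {
  stopifnot(inherits(model, "treatment_model"))
  if (!is.matrix(X) || ncol(X) != 10L)
    stop("`X` must be a matrix with 10 columns")
  lp <- model$intercept + drop(X[, 1:7, drop = FALSE] %*% model$slopes)
  p <- stats::plogis(lp)
  as.integer(stats::rbinom(nrow(X), 1L, p))
}

#' Generate Weibull event times by inverting the cumulative hazard
#'
#' Event times are `T = (-log(u) / (lambda * exp(LP)))^(1/eta)` with
#' `u ~ U(0,1)` and linear predictor
#' `LP = beta_treat * z + b' x[4:10]`, i.e. a Weibull
#' proportional-hazards model with shape `eta` and per-subject scale
#' `(lambda * exp(LP))^(-1/eta)`. Draws of `u` that underflow to 0 are
#' resampled so `log(u)` is always defined.
#'
#' @param X Covariate matrix with 10 columns.
#' @param Z Treatment indicator vector (0/1), length `nrow(X)`.
#' @param model An [outcome_model()].
#' @return Positive numeric vector of event times.
#' @export
generate_event_times <- function(X, Z, model) {
  stopifnot(inherits(model, "outcome_model"))
  if (!is.matrix(X) || ncol(X) != 10L)
    stop("`X` must be a matrix with 10 columns")
  if (length(Z) != nrow(X))
    stop("`Z` must have one element per row of `X`")
  lp <- model$beta_treat * Z +
    drop(X[, 4:10, drop = FALSE] %*% model$slopes)
  n <- nrow(X)
  u <- stats::runif(n)
  while (any(u == 0)) u[u == 0] <- stats::runif(sum(u == 0))
  (-log(u) / (model$lambda * exp(lp)))^(1 / model$eta)
}

#' Simulate one cohort
#'
#' Generates covariates, assigns treatment, and draws an uncensored event
#' time for every subject (the event indicator is identically 1; the column
#' is carried so the estimators also apply to real, censored data).
#'
#' @param n Number of subjects.
#' @param tmodel A [treatment_model()].
#' @param omodel An [outcome_model()].
#' @return A `data.frame` of class `ps_cohort` with columns `id`,
#'   `x1`..`x10`, `z`, `time`, `event`.
#' @export
generate_cohort <- function(n, tmodel, omodel) {
  X <- generate_covariates(n)
  Z <- assign_treatment(X, tmodel)
  times <- generate_event_times(X, Z, omodel)
  out <- data.frame(id = seq_len(as.integer(n)), X, z = Z, time = times,
                    event = 1L)
  class(out) <- c("ps_cohort", "data.frame")
  out
}

#' Extract the covariate matrix of a cohort
#' @param cohort A cohort `data.frame` with columns `x1`..`x10`.
#' @return Numeric matrix `n x 10`.
#' @export
cohort_covariates <- function(cohort) {
  as.matrix(cohort[, paste0("x", 1:10), drop = FALSE])
}

#' Write / read a cohort as CSV
#'
#' Plain CSV with columns `id, x1..x10, z, time, event`.
#' @param cohort Cohort `data.frame`.
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path)
  need <- c("id", paste0("x", 1:10), "z", "time", "event")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "))
  class(out) <- c("ps_cohort", "data.frame")
  out
}
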