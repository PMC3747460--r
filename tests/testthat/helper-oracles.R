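# Independent oracles used by the estimator tests. These re-derive the Cox
# partial likelihood and the sandwich variance from first principles and are
# deliberately written without reference to the package's fitting path
# (which delegates to survival::coxph).

# Log partial likelihood for a univariate Cox model (no ties, Breslow form;
# identical to Efron when all event times are distinct).
cox_log_partial_lik <- function(beta, time, z, event = rep(1, length(time))) {
  ord <- order(time, decreasing = TRUE)
  tt <- time[ord]; zz <- z[ord]; ee <- event[ord]
  risk <- cumsum(exp(beta * zz))  # risk set of the i-th largest time
  sum((beta * zz - log(risk))[ee == 1])
}

# Grid-search maximizer of the partial likelihood. The partial likelihood is
# concave in beta, so a coarse pass plus a fine pass around the coarse
# argmax locates the global maximum to the fine step.
cox_grid_mle <- function(time, z, event = rep(1, length(time)),
                         lower = -3, upper = 3) {
  coarse <- seq(lower, upper, by = 1e-3)
  lp <- vapply(coarse, cox_log_partial_lik, numeric(1), time, z, event)
  b0 <- coarse[which.max(lp)]
  fine <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-5)
  lp <- vapply(fine, cox_log_partial_lik, numeric(1), time, z, event)
  fine[which.max(lp)]
}

# Hand-assembled score residuals, observed information, and cluster-robust
# sandwich variance for a univariate Cox model with all subjects
# experiencing events and no tied times.
cox_sandwich_oracle <- function(time, z, cluster, beta) {
  n <- length(time)
  ebz <- exp(beta * z)
  # at each event time t_k: S0 = sum_{t_j >= t_k} e^{beta z_j}, S1, xbar
  S0 <- S1 <- S2 <- numeric(n)
  for (k in seq_len(n)) {
    r <- time >= time[k]
    S0[k] <- sum(ebz[r])
    S1[k] <- sum((z * ebz)[r])
    S2[k] <- sum((z^2 * ebz)[r])
  }
  xbar <- S1 / S0
  info <- sum(S2 / S0 - xbar^2)
  U <- numeric(n)
  for (i in seq_len(n)) {
    at_risk_of <- time <= time[i]  # event times whose risk set contains i
    U[i] <- (z[i] - xbar[i]) -
      sum(ebz[i] * (z[i] - xbar[at_risk_of]) / S0[at_risk_of])
  }
  Ug <- tapply(U, cluster, sum)
  list(score_residuals = U, info = info,
       robust_var = sum(Ug^2) / info^2)
}

# Closed-form Weibull survival function of the data-generating process.
weibull_survival <- function(t, lp, lambda = 2e-5, eta = 2) {
  exp(-lambda * exp(lp) * t^eta)
}

# Small simulated cohort under the study models.
make_cohort <- function(n, beta, prop = 0.25, seed = 1,
                        outcome_cov_slopes = pshazard:::outcome_slopes()) {
  set.seed(seed)
  tm <- treatment_model(calibrate_treatment_intercept(prop))
  om <- outcome_model(beta, slopes = outcome_cov_slopes)
  generate_cohort(n, tm, om)
}
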