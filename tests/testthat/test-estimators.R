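test_that("Cox engine matches grid-search partial-likelihood maximization", {
  # fixed toy dataset plus randomized small datasets
  set.seed(201)
  for (k in 1:10) {
    n <- sample(20:50, 1)
    z <- rbinom(n, 1, 0.5)
    if (sum(z) == 0 || sum(z) == n) z[1:2] <- c(0, 1)
    tt <- rexp(n, rate = exp(0.5 * z))
    fit <- fit_cox(tt, rep(1, n), z)
    expect_lt(abs(fit$loghr - cox_grid_mle(tt, z)), 1e-4)
  }
})

test_that("partial likelihood is invariant to time rescaling", {
  set.seed(211)
  n <- 60
  z <- rep(0:1, 30)
  tt <- rexp(n, exp(0.3 * z))
  f1 <- fit_cox(tt, rep(1, n), z)
  f2 <- fit_cox(tt * 37.5, rep(1, n), z)
  expect_equal(f1$loghr, f2$loghr, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("engine validates inputs and flags degenerate fits", {
  expect_error(fit_cox(1:4, c(1, 1, 1, 1), c(1, 1, 1, 1)), "each treatment arm")
  expect_error(fit_cox(1:4, c(0, 0, 1, 1), c(0, 0, 1, 1), weights = rep(1, 4),
                       variance = "model"), "robust")
  expect_error(fit_cox(1:4, rep(1, 4), c(0, 0, 1, 1), variance = "cluster"),
               "cluster")
})

test_that("cluster-robust sandwich equals the hand-assembled score-residual form", {
  # fixed 20-subject dataset, 10 clusters of 2
  set.seed(221)
  n <- 20
  z <- rep(c(1, 0), 10)
  tt <- round(rexp(n, exp(0.4 * z)), 6)
  cl <- rep(1:10, each = 2)
  fit <- fit_cox(tt, rep(1, n), z, cluster = cl, variance = "cluster")
  oracle <- cox_sandwich_oracle(tt, z, cl, fit$loghr)
  expect_equal(fit$se^2, oracle$robust_var, tolerance = 1e-10)

  # every subject its own cluster == unclustered robust variance
  f_self <- fit_cox(tt, rep(1, n), z, cluster = seq_len(n),
                    variance = "cluster")
  f_rob <- fit_cox(tt, rep(1, n), z, variance = "robust")
  expect_equal(f_self$se, f_rob$se, tolerance = 1e-12)
  oracle_u <- cox_sandwich_oracle(tt, z, seq_len(n), f_rob$loghr)
  expect_equal(f_rob$se^2, oracle_u$robust_var, tolerance = 1e-10)
})

test_that("naive and robust matched analyses share one point estimate", {
  co <- make_cohort(3000, log(1.5), prop = 0.25, seed = 231)
  ps <- fit_propensity_model(cohort_covariates(co), co$z)
  set.seed(232)
  m <- greedy_caliper_match(ps$logit_ps, co$z)
  naive <- estimate_matched(co, m, "naive")
  robust <- estimate_matched(co, m, "robust")
  strat <- estimate_matched(co, m, "stratified")
  expect_equal(naive$loghr, robust$loghr, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(naive$se, robust$se)))
  expect_false(isTRUE(all.equal(naive$loghr, strat$loghr)))
  expect_identical(naive$method, "matched-naive")
  expect_identical(robust$method, "matched-robust")
  expect_identical(strat$method, "matched-stratified")
})

test_that("pooled stratification averages the stratum-specific log-hazard ratios", {
  co <- make_cohort(4000, log(1.5), prop = 0.25, seed = 241)
  ps <- fit_propensity_model(cohort_covariates(co), co$z)
  st <- quintile_strata(ps$ps)
  pooled <- estimate_stratified(co, st, "pooled")
  # independent route: five stratum-specific survival::coxph fits
  coefs <- ses <- numeric(5)
  for (k in 1:5) {
    sel <- st$stratum == k
    f <- survival::coxph(survival::Surv(time, event) ~ z, data = co[sel, ],
                         ties = "efron")
    coefs[k] <- coef(f)
    ses[k] <- sqrt(f$var[1, 1])
  }
  expect_equal(pooled$loghr, mean(coefs), tolerance = 1e-8)
  expect_equal(pooled$se, sqrt(sum(ses^2)) / 5, tolerance = 1e-8)

  iv <- estimate_stratified(co, st, "pooled", pooling = "invvar")
  w <- 1 / ses^2
  expect_equal(iv$loghr, sum(w * coefs) / sum(w), tolerance = 1e-8)

  adj <- estimate_stratified(co, st, "adjusted")
  strf <- estimate_stratified(co, st, "stratified")
  expect_identical(adj$method, "strat-adjusted")
  expect_identical(strf$method, "strat-stratified")
})

test_that("IPTW with unit weights equals the unweighted robust fit", {
  co <- make_cohort(1500, log(1.25), prop = 0.25, seed = 251)
  w1 <- structure(list(w = rep(1, nrow(co)), estimand = "ATE"),
                  class = "iptw_weights")
  f_w <- estimate_iptw(co, w1)
  f_u <- fit_cox(co$time, co$event, co$z, variance = "robust")
  expect_equal(f_w$loghr, f_u$loghr, tolerance = 1e-10)
  expect_equal(f_w$se, f_u$se, tolerance = 1e-10)
})

test_that("covariate adjustment with a constant PS reduces to the univariate fit", {
  co <- make_cohort(800, log(1.5), prop = 0.25, seed = 261)
  f_c <- estimate_covadj(co, rep(0.25, nrow(co)))
  f_u <- fit_cox(co$time, co$event, co$z, variance = "model")
  expect_equal(f_c$loghr, f_u$loghr, tolerance = 1e-8)
})

test_that("IPTW recovers the conditional effect when nothing confounds", {
  # zero covariate effects in the outcome model: marginal == conditional,
  # and the ATE-weighted fit is unbiased for beta_treat
  set.seed(271)
  beta <- log(1.25)
  ests <- replicate(100, {
    co <- make_cohort(1500, beta, prop = 0.25, seed = sample.int(1e6, 1),
                      outcome_cov_slopes = rep(0, 7))
    ps <- fit_propensity_model(cohort_covariates(co), co$z)
    estimate_iptw(co, iptw_weights(ps$ps, co$z, "ATE"))$loghr
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - beta), 4 * mc_se)
})

test_that("marginal methods track their calibrated truth; conditional methods do not", {
  calib <- default_calibrations()
  # ATT framing, 25% treated, target marginal HR 2
  beta <- lookup_calibration(calib, 2, "ATT", 0.25)
  expect_false(is.na(beta))
  sc <- scenario_config(n_subjects = 10000, prop_treated = 0.25,
                        target_marginal_hr = 2, estimand = "ATT",
                        n_reps = 60, seed = 281L)
  res <- run_scenario(sc, methods = c("matched-naive", "matched-stratified",
                                      "iptw-att", "cov-adjust"),
                      beta_treat = beta)
  perf <- res$performance
  get <- function(m, col) perf[perf$method == m, col]
  # matched naive: minimal relative bias for the marginal ATT truth
  expect_lt(abs(get("matched-naive", "rel_bias_pct")), 5)
  expect_lt(abs(get("iptw-att", "rel_bias_pct")), 5)
  # pair-stratified and covariate-adjusted fits drift toward conditional values
  expect_gt(abs(get("matched-stratified", "bias")),
            abs(get("matched-naive", "bias")))
  expect_gt(abs(get("cov-adjust", "bias")),
            3 * get("cov-adjust", "mc_se_mean"))
  expect_gt(get("cov-adjust", "mean_loghr"), res$theta)
})

test_that("all nine estimators run on one cohort and agree on labels", {
  co <- make_cohort(2500, log(1.5), prop = 0.25, seed = 291)
  set.seed(292)
  est <- estimate_all(co)
  expect_identical(est$method, estimator_labels())
  expect_true(all(est$converged))
  expect_true(all(est$se > 0))
  expect_equal(est$ci_low, est$loghr - 1.96 * est$se, tolerance = 1e-12)
})
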