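test_that("propensity model is a valid maximum-likelihood logistic fit", {
  expect_error(fit_propensity_model(matrix(rnorm(40), 4), rep(1, 4)),
               "at least one treated")

  # null truth: fitted slopes within 4 Wald SEs of zero
  set.seed(101)
  X <- generate_covariates(1e5)
  z <- rbinom(1e5, 1, 0.3)
  ps <- fit_propensity_model(X, z)
  xd <- cbind(1, X[, 4:10])
  w <- ps$ps * (1 - ps$ps)
  se <- sqrt(diag(solve(crossprod(xd * sqrt(w)))))
  expect_true(all(abs(ps$coef[-1] / se[-1]) < 4))

  # logit consistency
  expect_equal(ps$logit_ps, qlogis(ps$ps), tolerance = 1e-12)

  # likelihood invariance to row replication
  set.seed(102)
  Xs <- generate_covariates(500)
  zs <- rbinom(500, 1, plogis(Xs[, 4]))
  f1 <- fit_propensity_model(Xs, zs)
  f2 <- fit_propensity_model(Xs[rep(1:500, 2), ], rep(zs, 2))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)

  # self-consistency: true model recovered at large n
  set.seed(103)
  Xl <- generate_covariates(2e5)
  tm <- treatment_model(calibrate_treatment_intercept(0.25))
  zl <- assign_treatment(Xl, tm)
  fl <- fit_propensity_model(Xl, zl, columns = 1:7)
  expect_equal(unname(fl$coef[-1]), tm$slopes, tolerance = 0.1)
})

test_that("greedy caliper matching obeys the caliper and the greedy order", {
  # within / outside caliper, two subjects
  one <- greedy_caliper_match(c(0, 0.05), c(1, 0), caliper_sd_multiple = Inf)
  expect_identical(nrow(one$pairs), 1L)

  res <- pshazard:::match_greedy_exact(0, 1L, 0.05, 2L, 0.1)
  expect_identical(res$treated, 1L)
  res2 <- pshazard:::match_greedy_exact(0, 1L, 0.5, 2L, 0.1)
  expect_identical(length(res2$treated), 0L)

  # toy set: both processing orders give the same pairs
  lt <- c(0.0, 0.2); lc <- c(0.01, 0.19, 0.5)
  for (ord in list(1:2, 2:1)) {
    r <- pshazard:::match_greedy_exact(lt[ord], ord, lc, 11:13, 0.1)
    got <- setNames(r$control, r$treated)
    expect_identical(got[order(names(got))], c(`1` = 11L, `2` = 12L))
  }

  # equidistant candidates resolve to the lower subject index
  r <- pshazard:::match_greedy_exact(0.5, 1L, c(0.4, 0.6), c(7L, 3L), 1)
  expect_identical(r$control, 7L)

  # infinite caliper with equal group sizes matches every treated subject
  set.seed(111)
  lps <- rnorm(40)
  zz <- rep(c(1, 0), 20)
  full <- greedy_caliper_match(lps, zz, caliper_sd_multiple = Inf)
  expect_identical(nrow(full$pairs), 20L)
  expect_identical(full$n_unmatched_treated, 0L)

  # no untreated subjects: empty sample with a warning
  expect_warning(empty <- greedy_caliper_match(rnorm(5), rep(1, 5)),
                 "no untreated")
  expect_identical(nrow(empty$pairs), 0L)
})

test_that("matching invariants hold on simulated cohorts and both matcher paths agree", {
  co <- make_cohort(6000, log(1.5), prop = 0.25, seed = 112)
  ps <- fit_propensity_model(cohort_covariates(co), co$z)
  set.seed(113)
  m <- greedy_caliper_match(ps$logit_ps, co$z)
  p <- m$pairs
  expect_true(all(co$z[p$treated] == 1))
  expect_true(all(co$z[p$control] == 0))
  expect_identical(anyDuplicated(c(p$treated, p$control)), 0L)
  expect_true(all(p$distance <= m$caliper + 1e-12))
  expect_equal(p$distance,
               abs(ps$logit_ps[p$treated] - ps$logit_ps[p$control]),
               tolerance = 1e-12)

  # fast sorted-scan path reproduces the exact quadratic scan
  tr <- which(co$z == 1); ctl <- which(co$z == 0)
  set.seed(113)
  ord <- sample(length(tr))
  fast <- pshazard:::match_greedy_fast(ps$logit_ps[tr][ord], tr[ord],
                                       ps$logit_ps[ctl], ctl, m$caliper)
  exact <- pshazard:::match_greedy_exact(ps$logit_ps[tr][ord], tr[ord],
                                         ps$logit_ps[ctl], ctl, m$caliper)
  expect_identical(fast, exact)
  expect_identical(sort(fast$control), sort(p$control))
})

test_that("matched samples balance the outcome-affecting covariates", {
  # mean absolute standardized difference of X4..X10 below 0.1 across reps
  set.seed(119)
  sdiffs <- replicate(50, {
    co <- make_cohort(4000, log(2), prop = 0.25,
                      seed = sample.int(1e6, 1))
    ps <- fit_propensity_model(cohort_covariates(co), co$z)
    m <- greedy_caliper_match(ps$logit_ps, co$z)
    X <- cohort_covariates(co)[, 4:10]
    xt <- X[m$pairs$treated, , drop = FALSE]
    xc <- X[m$pairs$control, , drop = FALSE]
    d <- (colMeans(xt) - colMeans(xc)) /
      sqrt((apply(xt, 2, var) + apply(xc, 2, var)) / 2)
    mean(abs(d))
  })
  expect_lt(mean(sdiffs), 0.1)
})

test_that("quintile stratification uses full-sample 20th..80th percentiles", {
  expect_error(quintile_strata(runif(4)), "at least 5")

  s10 <- quintile_strata(seq(0.1, 1, by = 0.1))
  expect_identical(as.integer(table(s10$stratum)), rep(2L, 5))

  set.seed(121)
  e <- runif(10000)
  s <- quintile_strata(e)
  expect_identical(as.integer(table(s$stratum)), rep(2000L, 5))
  # brute-force rank check: stratum = ceiling(rank / 2000)
  expect_identical(s$stratum, as.integer(ceiling(rank(e) / 2000)))
  # labels non-decreasing in e
  expect_true(all(diff(s$stratum[order(e)]) >= 0))
})

test_that("IPTW weights follow the ATE and ATT formulas", {
  expect_equal(iptw_weights(0.5, 1, "ATE")$w, 2)
  expect_equal(iptw_weights(0.25, 0, "ATE")$w, 4 / 3)
  expect_equal(iptw_weights(0.25, 0, "ATT")$w, 1 / 3)
  expect_equal(iptw_weights(0.9, 1, "ATT")$w, 1)
  expect_error(iptw_weights(c(0, 0.5), c(0, 1), "ATE"), "strictly between")

  set.seed(131)
  e <- runif(200, 0.05, 0.95)
  z <- rbinom(200, 1, e)
  wa <- iptw_weights(e, z, "ATE")$w
  expect_true(all(wa >= 1))
  wt <- iptw_weights(e, z, "ATT")$w
  expect_true(all(wt[z == 1] == 1))
  expect_true(all(wt >= 0))
})

test_that("conditioning designs tabulate per subject for export", {
  co <- make_cohort(500, 0, prop = 0.25, seed = 151)
  ps <- fit_propensity_model(cohort_covariates(co), co$z)
  set.seed(152)
  m <- greedy_caliper_match(ps$logit_ps, co$z)
  st <- quintile_strata(ps$ps)
  tab <- design_table(co, matched = m, strata = st,
                      weights_ate = iptw_weights(ps$ps, co$z, "ATE"),
                      weights_att = iptw_weights(ps$ps, co$z, "ATT"))
  expect_identical(nrow(tab), nrow(co))
  expect_identical(sum(!is.na(tab$pair)), 2L * nrow(m$pairs))
  # each pair label appears exactly twice, once per arm
  expect_true(all(table(tab$pair) == 2))
  expect_true(all(tab$w_att[tab$z == 1] == 1))
  expect_identical(tab$stratum, st$stratum)
})

test_that("expected ATT weight mass on controls equals the expected treated count", {
  # with the true propensity score, E[sum_{z=0} e/(1-e)] = E[#treated]
  set.seed(141)
  diffs <- replicate(200, {
    X <- generate_covariates(1000)
    tm <- treatment_model(calibrate_treatment_intercept(0.25))
    e <- plogis(tm$intercept + drop(X[, 1:7] %*% tm$slopes))
    z <- rbinom(1000, 1, e)
    w <- iptw_weights(e, z, "ATT")$w
    sum(w[z == 0]) - sum(z)
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})
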