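# pshazard

Monte Carlo simulation framework for studying how well propensity score
methods estimate **marginal hazard ratios** from time-to-event data, and a
small toolkit of the estimators themselves for use on real survival data.

## The scientific problem

Observational treatment comparisons must remove confounding. With the
propensity score `e(x) = Pr(Z = 1 | X = x)` there are four standard
designs: 1:1 matching on the score, stratification on its quintiles,
inverse probability of treatment weighting (IPTW), and covariate
adjustment using the score. For survival outcomes the effect is a hazard
ratio — and hazard ratios are **non-collapsible**: the subject-level
(conditional) hazard ratio `exp(beta)` of a proportional-hazards model
differs from the population-average (marginal) hazard ratio even without
confounding, the marginal effect lying closer to the null. Matching and
IPTW estimate marginal effects; stratified, pair-stratified and
covariate-adjusted Cox models estimate conditional ones. Comparing the
designs fairly therefore requires simulated data whose *marginal* hazard
ratio is controlled.

`pshazard` provides:

* **Data generation** — ten independent standard-normal covariates (three
  instruments, four confounders, three outcome-only; effect sizes
  log 1.25 / log 1.5 / log 1.75 / log 2), logistic treatment selection
  with a prevalence-calibrated intercept, and Weibull event times
  `T = (-log u / (lambda e^LP))^(1/eta)` with `lambda = 2e-5`, `eta = 2`.
* **Marginal calibration** — `calibrate_conditional_beta()` finds the
  conditional log-hazard ratio `beta_treat` that induces a target marginal
  hazard ratio (ATE framing: whole population; ATT framing: the treated),
  by potential-outcomes simulation and bisection. A precomputed table for
  the full scenario grid ships with the package
  (`default_calibrations()`).
* **Nine estimators** — naive / robust / pair-stratified Cox in the
  matched sample; adjusted / pooled / stratified Cox over score quintiles;
  ATE- and ATT-weighted Cox with robust variance; covariate adjustment on
  the score. All built on `survival::coxph` and usable on any
  `(time, event, z, x1..x10)` data frame.
* **Performance battery** — bias, relative bias, MSE, mean SE, empirical
  SD, SE/SD ratio, 95% CI coverage and length, per method per scenario,
  with seeded, parallel-safe replication (`run_scenario()`, `run_grid()`).

## Worked example

Simulate one 25%-treated scenario whose true marginal ATT hazard ratio is
2, using the shipped calibration, and compare four estimators over 50
replicates of n = 10,000:

```r
library(pshazard)

sc <- scenario_config(n_subjects = 10000, prop_treated = 0.25,
                      target_marginal_hr = 2, estimand = "ATT",
                      n_reps = 50, seed = 7L)
res <- run_scenario(sc, methods = c("matched-naive", "matched-robust",
                                    "iptw-att", "cov-adjust"),
                    calibrations = default_calibrations())
res
#> Scenario: n=10000, 25% treated, target marginal HR 2 (ATT), 50 reps, seed 7
#> beta_treat = 1.19903, true marginal log-HR = 0.69315
#> avg matched pairs 2354.1 (94.2% of treated)
#>           method n_reps mean_loghr    bias rel_bias_pct      mse mean_se
#> 1  matched-naive     50     0.7137 0.02057       2.9677 0.001073 0.03023
#> 2 matched-robust     50     0.7137 0.02057       2.9677 0.001073 0.02739
#> 3       iptw-att     50     0.6954 0.00229       0.3303 0.000394 0.02783
#> 4     cov-adjust     50     0.9465 0.25331      36.5442 0.064745 0.02584
#>   sd_loghr se_sd_ratio coverage ci_length_hr ci_length_log mc_se_mean
#> 1  0.02574       1.174     0.90       0.2422        0.1185   0.003641
#> 2  0.02574       1.064     0.88       0.2194        0.1074   0.003641
#> 3  0.01992       1.397     0.98       0.2188        0.1091   0.002817
#> 4  0.02436       1.061     0.00       0.2612        0.1013   0.003445
```

The matched estimators and IPTW-ATT recover the marginal truth
(log 2 ≈ 0.693) with relative bias of 3% or less at 50 replicates, while
covariate adjustment using the propensity score — a conditional model —
overshoots by ~37% on the log scale and its 95% intervals never cover the
marginal truth. The conditional hazard ratio that *generates* these data
is exp(1.199) ≈ 3.3: non-collapsibility at work. The naive matched SE
overstates the sampling variability (SE/SD 1.17) where the pair-clustered
robust SE (1.06) is better calibrated.

The same machinery scales to the full factorial study:

```r
g <- run_grid(prevalences = c(0.05, 0.10, 0.25),
              marginal_hrs = c(0.8, 1, 1.10, 1.25, 1.50, 1.75, 2),
              estimand = "ATT", n_subjects = 10000, n_reps = 200,
              seed = 1L, calibrations = default_calibrations(),
              out_dir = "grid-out")
```

A command-line front end (`exec/pshazard`) exposes `simulate`, `grid`,
`calibrate`, and `report` subcommands over YAML/JSON configs and CSV
outputs.

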