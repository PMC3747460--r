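---
title: "Simulating and estimating marginal hazard ratios with propensity scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and estimating marginal hazard ratios with propensity scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshazard)
```

## The problem

Propensity score methods — matching, stratification, inverse probability of
treatment weighting (IPTW), and covariate adjustment — are the standard
toolkit for estimating treatment effects from observational data. For
time-to-event outcomes the effect is usually summarized as a hazard ratio,
and hazard ratios are *non-collapsible*: even without confounding, the
subject-level (conditional) hazard ratio from a covariate-adjusted model
differs from the population-average (marginal) hazard ratio that a
randomized trial would report, with the marginal effect closer to the null.
A simulation study of these methods therefore has to control the *marginal*
hazard ratio of its data-generating process, which is only implicitly
determined by the conditional effect the generator actually uses.

`pshazard` implements that simulation framework end to end: the
data-generating process, the conditional-to-marginal calibration, nine Cox
model estimators, and the Monte Carlo performance battery.

## Data-generating process

Each subject has ten independent standard-normal covariates. Three affect
only treatment selection (`x1`–`x3`), four affect both treatment and
outcome and hence confound (`x4`–`x7`), and three affect only the outcome
(`x8`–`x10`). Effects come in four magnitudes — weak log(1.25), moderate
log(1.5), strong log(1.75), very strong log(2) — arranged as:

* treatment selection (logistic): `logit(p) = a0 + aW x1 + aM x2 + aS x3 +
  aW x4 + aM x5 + aS x6 + aVS x7`;
* outcome (Weibull proportional hazards): `LP = beta_treat z + aW x4 +
  aM x5 + aS x6 + aVS x7 + aW x8 + aM x9 + aS x10`, with event time
  `T = (-log u / (lambda e^LP))^(1/eta)`, `u ~ U(0,1)`, `lambda = 0.00002`,
  `eta = 2` (the standard inverse-cumulative-hazard construction for
  proportional-hazards data).

Every subject experiences the event (`event = 1`); the generator emulates a
fully observed cohort. The estimator functions still carry an event
indicator so they apply unchanged to real, censored data, but none of the
simulation results here say anything about censoring, and likewise nothing
about non-normal or correlated covariates, treatment effect heterogeneity,
or model misspecification of the propensity model — the propensity model
fitted in the simulations (logistic in `x4`–`x10`) contains the true
confounders by construction.

### Treatment prevalence

The intercept `a0` is chosen once per prevalence so that the *expected*
prevalence equals the target (5%, 10%, or 25%). Because the covariates are
independent standard normals, the treatment linear predictor is exactly
normal with variance equal to the sum of squared slopes, so the expected
prevalence is a one-dimensional integral; `calibrate_treatment_intercept()`
evaluates it by quadrature and inverts it with a bracketing root finder to
1e-6 on the probability scale. The realized prevalence in any one cohort is
then binomial — it is matched in expectation, not forced per sample.

```{r}
calibrate_treatment_intercept(0.25)
```

### Degenerate inputs

Uniform draws that underflow to exactly 0 are resampled (so `log(u)` is
always defined); `n = 0` returns an empty, correctly shaped matrix;
propensity scores of exactly 0 or 1 are an error for weighting rather than
silently producing infinite weights.

## Calibrating the conditional effect

`estimate_marginal_loghr()` measures the marginal effect induced by a
conditional `beta_treat`: simulate a cohort, give every subject *two*
potential event times (treatment forced off and forced on, same covariates,
independent uniforms per arm — the description does not couple them, and
the stacked-sample Cox point estimate is unaffected in expectation), stack
the `2n` records, and fit a univariate Cox model on the arm indicator. For
the ATT framing the stacked sample is first restricted to subjects whose
realized assignment was treatment. The mean coefficient across replicates
estimates the marginal log hazard ratio, with a Monte Carlo SE.

`calibrate_conditional_beta()` inverts this map by bisection, which is
safe because the marginal effect is monotone in the conditional one. The
initial bracket `log(target) ± (0.5 |log(target)| + 0.1)` is widened if
needed; widening past ±5 on the log scale aborts, since no reasonable
configuration of this generator needs a conditional hazard ratio beyond
e^5. Iteration stops when the achieved marginal log hazard ratio is within
`tol` (default 0.005) of the target — tighter tolerances would chase Monte
Carlo noise at the default fidelity of 1000 replicates per evaluation.

The package ships a calibration table (`default_calibrations()`) covering
the full scenario grid — 3 prevalences × 7 target marginal hazard ratios ×
both estimand framings — built by `scripts/build_calibrations.R` at 500
replicates of n = 10,000 per bisection evaluation. A target hazard ratio
of 1 maps to `beta_treat = 0` exactly (with no treatment effect the two
potential-outcome arms share one distribution), so those entries are
analytic. Cohort size per calibration replicate defaults to the scenario's
n = 10,000, consistent with the main simulation; the replicate count per
evaluation is configurable because it is the fidelity/runtime dial.

ATE and ATT calibrations genuinely differ under this generator: the treated
subpopulation has a shifted covariate distribution, so the same conditional
effect marginalizes differently over it.

## The nine estimators

All estimators are Cox models for the treatment effect, differing in the
sample, the conditioning, and the variance:

| label | sample | model | variance |
|---|---|---|---|
| `matched-naive` | 1:1 matched | `~ z` | model-based |
| `matched-robust` | 1:1 matched | `~ z` | pair-clustered sandwich |
| `matched-stratified` | 1:1 matched | `~ z + strata(pair)` | model-based |
| `strat-adjusted` | full | `~ z + stratum (factor)` | model-based |
| `strat-pooled` | full | 5 stratum-wise `~ z`, averaged | pooled |
| `strat-stratified` | full | `~ z + strata(stratum)` | model-based |
| `iptw-ate` | full, ATE-weighted | `~ z` | robust sandwich |
| `iptw-att` | full, ATT-weighted | `~ z` | robust sandwich |
| `cov-adjust` | full | `~ z + ps` | model-based |

The first two and the IPTW pair are marginal estimators; the others
condition (on pairs, strata, or the score itself) and estimate conditional
effects. Quintile stratification is additionally *coarse*: five strata
remove only about 90% of the confounding carried by a continuous score,
so the three stratification estimators keep a small residual confounding
bias that is visible even at a null treatment effect, where
non-collapsibility plays no role — the test suite measures it at about
+0.06 on the log scale under the default generator at 25% prevalence. The engine is `survival::coxph` with Efron tie handling (ties are
almost surely absent for continuous simulated times, but the choice is
pinned for real data); the test suite verifies the engine against a
grid-search maximizer of the partial likelihood written from first
principles, and the sandwich variance against hand-assembled score
residuals.

Matching is greedy nearest-neighbour on the logit of the propensity score
within a caliper of 0.2 standard deviations of that logit. Where a single
"SD of the logit propensity score" must be pinned down, the default is the
pooled within-group SD `sqrt((s²_treated + s²_untreated)/2)` — the
convention of the caliper-width literature the design follows — with the
full-sample SD available as an option. Treated subjects are processed in
random (seeded) order by default, the common convention for greedy matching
macros; deterministic orders (descending score, data order) are options.
Equidistant candidates resolve to the lower subject index. Quintile cut
points use linear interpolation of the order statistics (`quantile`
type 7) with boundary values assigned to the lower stratum; with a
continuous score the dialect is immaterial, but it is pinned for
reproducibility. IPTW uses raw weights — no truncation or stabilization.

For `strat-pooled`, "pooling or averaging" the five stratum effects is read
as the unweighted mean (SE `sqrt(sum se_k^2)/5`); inverse-variance pooling
is provided as an option since the phrase admits that reading too. Strata
with no events in one arm are dropped from the pooled average with a
warning — essentially impossible at n = 10,000, but pinned for small data.

## Performance metrics

Per method and scenario, across replicates: mean log-HR, bias, relative
bias (100 · bias/θ, omitted at θ = 0), MSE, mean estimated SE, empirical SD
of the estimates, the SE/SD ratio (1 = correctly calibrated variance
estimation), empirical 95% CI coverage, and mean CI length. CI length is
averaged on the hazard-ratio scale (exponentiated endpoints), matching how
such intervals are reported; the log-scale length is recorded alongside.
Confidence intervals are Wald intervals on the log scale with z = 1.96
exactly. An empirical coverage outside
`0.95 ± 1.96 sqrt(0.95·0.05/n_reps)` (0.9457–0.9543 at 10,000 replicates)
differs significantly from nominal.

Replicates where an estimator fails to converge are dropped per method,
not per replicate, and counted.

## Reproducibility and problem sizes

One master seed drives everything. Replicates use independent
L'Ecuyer-CMRG substreams, so a scenario's results are bit-identical whether
replicates run serially or across any number of forked workers, and any
single replicate can be regenerated alone.

The reference design — 21 scenarios × 10,000 replicates × 10,000 subjects —
is an overnight-scale computation. The package's own test tiers, chosen as
desk-scale defaults:

* matching yields: 100 cohorts of 10,000 per prevalence;
* the scaled-down grid reproduction: 21 ATT scenarios × 200 replicates of
  n = 10,000 for the four marginal estimators (Monte Carlo error of
  21-scenario averages is then far below the reproduction tolerances);
* property checks (collapsibility, attenuation, monotonicity, round-trip):
  cohorts of 1,500–10,000 with 30–150 replicates, asserted in multiples of
  the Monte Carlo SE.

Metric means scale as 1/sqrt(replicates), so these tiers reproduce the
reference quantities with proportionally wider noise bands; nothing about
the design changes with the tier.

Two aggregation subtleties are worth knowing. The absolute MSE level of
the (nearly unbiased) marginal estimators is `SD^2 + bias^2`, and its bias
component is governed almost entirely by how tightly the conditional
effect was calibrated to the marginal target — a calibration tolerance of
0.005 contributes at most ~2.5e-5, but a tolerance of 0.03 would roughly
double the MSE of the most precise estimators. SD-derived quantities (the
SE/SD ratio, projected Monte Carlo precision) are insensitive to the
calibration. And a maximum taken over many per-scenario SD estimates is
upward-biased at reduced replication (each SD carries ~5% noise at 200
replicates), so projected worst-case precision bounds are conservative at
desk scale.

## Known limitations

Uncensored outcomes only in the generator (the estimators accept censored
data, untested against censoring-induced phenomena); 1:1 greedy matching
only (no M:1, optimal, or with-replacement matching); no stabilized or
truncated weights; no survival-curve (absolute risk) comparisons. The
bisection treats each evaluation as exact up to its Monte Carlo SE; with
very small `n_mc_reps` the achieved-tolerance stopping rule can stop one
step early, which is why the shipped calibrations use 500 replicates per
evaluation and record the achieved value and its SE.
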