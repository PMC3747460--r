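#' Method labels for the nine hazard-ratio estimators
#' @return Character vector of the nine method labels.
#' @export
estimator_labels <- function() {
  c("matched-naive", "matched-robust", "matched-stratified",
    "strat-adjusted", "strat-pooled", "strat-stratified",
    "iptw-ate", "iptw-att", "cov-adjust")
}

effect_estimate <- function(method, loghr, se, converged = TRUE) {
  data.frame(method = method, loghr = loghr, se = se,
             ci_low = loghr - 1.96 * se, ci_high = loghr + 1.96 * se,
             converged = converged, stringsAsFactors = FALSE)
}

#' Common Cox proportional-hazards engine
#'
#' Fits a Cox model for the treatment effect with the structural options the
#' nine estimators need: extra covariates, baseline-hazard stratification,
#' observation weights, and model-based, robust (sandwich), or
#' cluster-robust variance. The partial likelihood uses Efron tie handling
#' (ties are almost surely absent for continuous simulated times); weighted
#' fits maximize the weighted partial likelihood with the weights entering
#' both the score and the sandwich.
#'
#' @param time Event/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param z Treatment indicator (0/1).
#' @param covariates Optional numeric matrix / data frame of additional
#'   regression covariates.
#' @param strata Optional baseline-hazard stratification variable (e.g.
#'   matched-pair id or propensity-score stratum).
#' @param cluster Optional cluster variable for the cluster-robust sandwich
#'   variance (score residuals summed within clusters).
#' @param weights Optional non-negative observation weights (force a robust
#'   variance).
#' @param variance `"model"` (inverse observed information), `"robust"`
#'   (unclustered sandwich), or `"cluster"` (sandwich with `cluster`).
#' @param method Label stored in the returned estimate.
#' @return One-row data frame (an effect estimate): `method`, `loghr`, `se`,
#'   `ci_low`, `ci_high` (Wald, log-HR scale, z = 1.96), `converged`.
#' @export
fit_cox <- function(time, event, z, covariates = NULL, strata = NULL,
                    cluster = NULL, weights = NULL,
                    variance = c("model", "robust", "cluster"),
                    method = "cox") {
  variance <- match.arg(variance)
  if (variance == "cluster" && is.null(cluster))
    stop("cluster-robust variance requires a `cluster` variable")
  if (!is.null(weights) && variance == "model")
    stop("weighted fits require a robust variance")
  z <- as.numeric(z)
  event <- as.numeric(event)
  if (sum(event[z == 1]) < 1 || sum(event[z == 0]) < 1)
    stop("need at least one event in each treatment arm (monotone likelihood)")
  dat <- data.frame(.time = time, .event = event, z = z)
  rhs <- "z"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- make.names(names(covariates))
    dat <- cbind(dat, covariates)
    rhs <- paste(c("z", names(covariates)), collapse = " + ")
  }
  if (!is.null(strata)) {
    dat$.strat <- strata
    rhs <- paste(rhs, "+ strata(.strat)")
  }
  if (variance == "cluster") {
    dat$.clus <- cluster
    rhs <- paste(rhs, "+ cluster(.clus)")
  }
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, weights = .w,
                    robust = variance != "model", ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)["z"])
  se <- sqrt(fit$var[1, 1])  # robust variance when requested, else model-based
  if (!is.finite(beta) || !is.finite(se)) converged <- FALSE
  effect_estimate(method, beta, se, converged)
}

matched_rows <- function(cohort, matched) {
  if (nrow(matched$pairs) == 0L) stop("matched sample is empty")
  idx <- c(matched$pairs$treated, matched$pairs$control)
  pair <- rep(seq_len(nrow(matched$pairs)), 2L)
  out <- cohort[idx, , drop = FALSE]
  out$.pair <- pair
  out
}

#' Treatment effect in the propensity-score matched sample
#'
#' Univariate Cox regression of survival on treatment within the matched
#' sample, in three variants: `"naive"` (model-based SE, treating matched
#' subjects as independent), `"robust"` (same point estimate with a
#' cluster-robust sandwich SE accounting for within-pair clustering), and
#' `"stratified"` (baseline hazard stratified on matched pairs, a
#' conditional model).
#'
#' @param cohort Cohort data frame (`z`, `time`, `event` columns).
#' @param matched A `matched_sample` from [greedy_caliper_match()].
#' @param variant `"naive"`, `"robust"`, or `"stratified"`.
#' @return One-row effect-estimate data frame.
#' @export
estimate_matched <- function(cohort, matched,
                             variant = c("naive", "robust", "stratified")) {
  variant <- match.arg(variant)
  dat <- matched_rows(cohort, matched)
  switch(variant,
    naive = fit_cox(dat$time, dat$event, dat$z, variance = "model",
                    method = "matched-naive"),
    robust = fit_cox(dat$time, dat$event, dat$z, cluster = dat$.pair,
                     variance = "cluster", method = "matched-robust"),
    stratified = fit_cox(dat$time, dat$event, dat$z, strata = dat$.pair,
                         variance = "model", method = "matched-stratified"))
}

#' Treatment effect under stratification on propensity-score quintiles
#'
#' Three variants: `"adjusted"` (single Cox fit with the stratum as a
#' five-level categorical covariate), `"pooled"` (five stratum-specific
#' univariate Cox fits whose log-hazard ratios are averaged), and
#' `"stratified"` (one Cox fit with stratum-specific baseline hazards). All
#' three are conditional models.
#'
#' For the pooled variant, strata without at least one event in each
#' treatment arm are dropped with a warning; fewer than two usable strata is
#' an error. The default pooling is the unweighted mean with
#' `SE = sqrt(sum(se_k^2))/K`; `pooling = "invvar"` uses inverse-variance
#' weights.
#'
#' @param cohort Cohort data frame.
#' @param strata A `stratum_assignment` from [quintile_strata()].
#' @param variant `"adjusted"`, `"pooled"`, or `"stratified"`.
#' @param pooling `"mean"` (default) or `"invvar"` for the pooled variant.
#' @return One-row effect-estimate data frame.
#' @export
estimate_stratified <- function(cohort, strata,
                                variant = c("adjusted", "pooled", "stratified"),
                                pooling = c("mean", "invvar")) {
  variant <- match.arg(variant)
  pooling <- match.arg(pooling)
  s <- strata$stratum
  if (variant == "adjusted") {
    dummies <- stats::model.matrix(~ factor(s))[, -1, drop = FALSE]
    colnames(dummies) <- paste0("stratum", sort(unique(s))[-1])
    return(fit_cox(cohort$time, cohort$event, cohort$z,
                   covariates = as.data.frame(dummies), variance = "model",
                   method = "strat-adjusted"))
  }
  if (variant == "stratified") {
    return(fit_cox(cohort$time, cohort$event, cohort$z, strata = s,
                   variance = "model", method = "strat-stratified"))
  }
  # pooled: stratum-specific univariate fits, then average
  labs <- sort(unique(s))
  coefs <- ses <- numeric(0)
  conv <- TRUE
  for (k in labs) {
    sel <- s == k
    usable <- sum(cohort$event[sel & cohort$z == 1]) >= 1 &&
      sum(cohort$event[sel & cohort$z == 0]) >= 1
    if (!usable) {
      warning("stratum ", k, " has no events in one arm; dropped from pooling")
      next
    }
    f <- fit_cox(cohort$time[sel], cohort$event[sel], cohort$z[sel],
                 variance = "model")
    coefs <- c(coefs, f$loghr)
    ses <- c(ses, f$se)
    conv <- conv && f$converged
  }
  if (length(coefs) < 2L)
    stop("fewer than 2 usable strata for the pooled estimator")
  if (pooling == "mean") {
    est <- mean(coefs)
    se <- sqrt(sum(ses^2)) / length(ses)
  } else {
    w <- 1 / ses^2
    est <- sum(w * coefs) / sum(w)
    se <- sqrt(1 / sum(w))
  }
  effect_estimate("strat-pooled", est, se, conv)
}

#' Treatment effect by inverse probability of treatment weighting
#'
#' Weighted univariate Cox regression of survival on treatment, with an
#' unclustered robust sandwich variance.
#'
#' @param cohort Cohort data frame.
#' @param weights An `iptw_weights` object (or bare numeric weights).
#' @return One-row effect-estimate data frame, labelled `iptw-ate` or
#'   `iptw-att` according to the weights' estimand.
#' @export
estimate_iptw <- function(cohort, weights) {
  if (inherits(weights, "iptw_weights")) {
    lab <- paste0("iptw-", tolower(weights$estimand))
    w <- weights$w
  } else {
    lab <- "iptw"
    w <- weights
  }
  fit_cox(cohort$time, cohort$event, cohort$z, weights = w,
          variance = "robust", method = lab)
}

#' Treatment effect by covariate adjustment using the propensity score
#'
#' Cox regression of survival on the treatment indicator and the propensity
#' score; the treatment coefficient (a conditional log-hazard ratio) is
#' returned with a model-based SE.
#'
#' @param cohort Cohort data frame.
#' @param ps A `ps_model` from [fit_propensity_model()] (or bare propensity
#'   scores).
#' @return One-row effect-estimate data frame.
#' @export
estimate_covadj <- function(cohort, ps) {
  e <- if (inherits(ps, "ps_model")) ps$ps else ps
  fit_cox(cohort$time, cohort$event, cohort$z,
          covariates = data.frame(ps = e), variance = "model",
          method = "cov-adjust")
}

#' Run a set of estimators on one cohort
#'
#' Fits the propensity model, builds the conditioning designs needed by the
#' requested methods (matched sample, quintile strata, ATE/ATT weights), and
#' returns the stacked effect estimates.
#'
#' @param cohort Cohort data frame.
#' @param methods Subset of [estimator_labels()].
#' @param ps_columns Covariate columns for the propensity model.
#' @param caliper_sd_multiple Caliper width multiple for matching.
#' @return Data frame of effect estimates (one row per method) with
#'   attributes `n_pairs` (matched pairs formed) and `n_treated`.
#' @export
estimate_all <- function(cohort, methods = estimator_labels(),
                         ps_columns = 4:10, caliper_sd_multiple = 0.2) {
  bad <- setdiff(methods, estimator_labels())
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  ps <- fit_propensity_model(cohort_covariates(cohort), cohort$z,
                             columns = ps_columns)
  out <- list()
  n_pairs <- NA_integer_
  if (any(grepl("^matched", methods))) {
    m <- greedy_caliper_match(ps$logit_ps, cohort$z, caliper_sd_multiple)
    n_pairs <- nrow(m$pairs)
    for (v in c("naive", "robust", "stratified"))
      if (paste0("matched-", v) %in% methods)
        out[[paste0("matched-", v)]] <- estimate_matched(cohort, m, v)
  }
  if (any(grepl("^strat", methods))) {
    st <- quintile_strata(ps$ps)
    for (v in c("adjusted", "pooled", "stratified"))
      if (paste0("strat-", v) %in% methods)
        out[[paste0("strat-", v)]] <- estimate_stratified(cohort, st, v)
  }
  if ("iptw-ate" %in% methods)
    out[["iptw-ate"]] <- estimate_iptw(cohort, iptw_weights(ps$ps, cohort$z, "ATE"))
  if ("iptw-att" %in% methods)
    out[["iptw-att"]] <- estimate_iptw(cohort, iptw_weights(ps$ps, cohort$z, "ATT"))
  if ("cov-adjust" %in% methods)
    out[["cov-adjust"]] <- estimate_covadj(cohort, ps)
  res <- do.call(rbind, out[methods[methods %in% names(out)]])
  rownames(res) <- NULL
  attr(res, "n_pairs") <- n_pairs
  attr(res, "n_treated") <- sum(cohort$z == 1)
  res
}
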