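#' Fit the propensity score model
#'
#' Maximum-likelihood logistic regression of treatment status on a set of
#' covariate columns. The default column set X4..X10 is the seven covariates
#' that affect the outcome; conditioning the propensity model on
#' outcome-affecting covariates is the variable-selection strategy used
#' throughout the simulation.
#'
#' @param X Covariate matrix (columns `x1`..`x10`) or a cohort data frame.
#' @param Z Treatment indicator (0/1). Omit when `X` is a cohort.
#' @param columns Indices of the covariate columns to include (default 4:10).
#' @return An object of class `ps_model` with elements `ps` (fitted
#'   probabilities), `logit_ps`, `coef`.
#' @export
fit_propensity_model <- function(X, Z = NULL, columns = 4:10) {
  if (is.data.frame(X)) {
    if (is.null(Z)) Z <- X$z
    X <- cohort_covariates(X)
  }
  if (!is.matrix(X)) stop("`X` must be a matrix or cohort data frame")
  Z <- as.integer(Z)
  if (length(Z) != nrow(X)) stop("`Z` must match the rows of `X`")
  nt <- sum(Z == 1L)
  if (nt == 0L || nt == length(Z))
    stop("need at least one treated and one untreated subject")
  xd <- cbind(`(Intercept)` = 1, X[, columns, drop = FALSE])
  fit <- stats::glm.fit(xd, Z, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = 100))
  p <- fit$fitted.values
  # gradient of the log-likelihood at the optimum
  grad <- drop(crossprod(xd, Z - p))
  if (!fit$converged || sqrt(sum(grad^2)) > 1e-8 * max(1, length(Z)))
    stop("propensity model did not converge (gradient norm ",
         format(sqrt(sum(grad^2))), ")")
  eps <- 1e-12
  if (any(p < eps) || any(p > 1 - eps))
    stop("fitted propensity scores at 0/1: possible perfect separation")
  structure(list(ps = p, logit_ps = stats::qlogis(p),
                 coef = stats::coef(fit)),
            class = "ps_model")
}

# Caliper width on the logit scale: a multiple of either the pooled
# within-group SD, sqrt((s2_treated + s2_untreated)/2), or the full-sample SD.
caliper_width <- function(logit_ps, Z, caliper_sd_multiple,
                          sd_type = c("pooled", "overall")) {
  sd_type <- match.arg(sd_type)
  s <- switch(sd_type,
    pooled  = sqrt((stats::var(logit_ps[Z == 1]) +
                    stats::var(logit_ps[Z == 0])) / 2),
    overall = stats::sd(logit_ps))
  caliper_sd_multiple * s
}

# Exact greedy pass: for each treated subject (in processing order) scan all
# still-available controls. O(n_t * n_c); used for small problems and as the
# reference for the fast path. Ties broken by lower subject index
# (which.min returns the first minimum; controls are kept in index order).
match_greedy_exact <- function(lt, treated_idx, lc, control_idx, caliper) {
  avail <- rep(TRUE, length(lc))
  t_out <- integer(0); c_out <- integer(0); d_out <- numeric(0)
  for (k in seq_along(treated_idx)) {
    d <- abs(lc - lt[k])
    d[!avail] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= caliper) {
      avail[j] <- FALSE
      t_out <- c(t_out, treated_idx[k])
      c_out <- c(c_out, control_idx[j])
      d_out <- c(d_out, d[j])
    }
  }
  list(treated = t_out, control = c_out, distance = d_out)
}

# Fast greedy pass over controls sorted by logit-PS. Availability is tracked
# with "next available left/right" jump arrays with path compression, so each
# treated subject costs amortized near-constant time. Identical to the exact
# pass whenever logit distances are distinct (ties are measure-zero for
# continuous propensity scores).
match_greedy_fast <- function(lt, treated_idx, lc, control_idx, caliper) {
  m <- length(lc)
  o <- order(lc, control_idx)
  sl <- lc[o]; si <- control_idx[o]
  avail <- rep(TRUE, m)
  jr <- seq_len(m) + 1L  # jump right: candidate available position > i
  jl <- seq_len(m) - 1L  # jump left:  candidate available position < i
  nt <- length(treated_idx)
  t_out <- integer(nt); c_out <- integer(nt); d_out <- numeric(nt)
  np <- 0L
  for (k in seq_len(nt)) {
    x <- lt[k]
    pos <- findInterval(x, sl)
    # nearest available at or left of pos
    lj <- pos
    while (lj >= 1L && !avail[lj]) lj <- jl[lj]
    i <- pos
    while (i >= 1L && i > lj) { pi <- jl[i]; jl[i] <- lj; i <- pi }
    # nearest available right of pos
    rj <- pos + 1L
    while (rj <= m && !avail[rj]) rj <- jr[rj]
    i <- pos + 1L
    while (i <= m && i < rj) { ni <- jr[i]; jr[i] <- rj; i <- ni }
    ld <- if (lj >= 1L) x - sl[lj] else Inf
    rd <- if (rj <= m) sl[rj] - x else Inf
    if (ld <= rd) { j <- lj; d <- ld } else { j <- rj; d <- rd }
    if (is.finite(d) && d <= caliper) {
      avail[j] <- FALSE
      np <- np + 1L
      t_out[np] <- treated_idx[k]
      c_out[np] <- si[j]
      d_out[np] <- d
    }
  }
  list(treated = t_out[seq_len(np)], control = c_out[seq_len(np)],
       distance = d_out[seq_len(np)])
}

#' Greedy nearest-neighbour caliper matching on the logit propensity score
#'
#' Forms 1:1 matched pairs of treated and untreated subjects. Treated
#' subjects are processed one at a time (by default in random order, using
#' the current RNG state); each is matched without replacement to the
#' nearest still-unmatched untreated subject by absolute distance on the
#' logit propensity score, provided that distance does not exceed the
#' caliper. Treated subjects with no untreated subject within the caliper
#' remain unmatched and are excluded from the matched sample.
#'
#' The caliper is `caliper_sd_multiple` times the standard deviation of the
#' logit propensity score (default 0.2 times the pooled within-group SD).
#' Equidistant candidates are resolved in favour of the lower subject index.
#'
#' @param logit_ps Logit of the propensity score, one value per subject.
#' @param Z Treatment indicator (0/1).
#' @param caliper_sd_multiple Caliper width as a multiple of the logit-PS SD
#'   (default 0.2). `Inf` disables the caliper.
#' @param sd_type `"pooled"` (default) or `"overall"` SD for the caliper.
#' @param order Processing order for treated subjects: `"random"` (default),
#'   `"descending"` (by logit-PS), or `"data"`.
#' @return An object of class `matched_sample`: list with `pairs` (data frame
#'   of `treated`, `control` subject indices and logit `distance`),
#'   `caliper`, `n_treated`, `n_unmatched_treated`.
#' @export
greedy_caliper_match <- function(logit_ps, Z, caliper_sd_multiple = 0.2,
                                 sd_type = c("pooled", "overall"),
                                 order = c("random", "descending", "data")) {
  order <- match.arg(order)
  if (!is.numeric(caliper_sd_multiple) || caliper_sd_multiple <= 0)
    stop("`caliper_sd_multiple` must be positive")
  Z <- as.integer(Z)
  stopifnot(length(Z) == length(logit_ps))
  treated_idx <- which(Z == 1L)
  control_idx <- which(Z == 0L)
  if (length(control_idx) == 0L) {
    warning("no untreated subjects: matched sample is empty")
    return(structure(list(
      pairs = data.frame(treated = integer(0), control = integer(0),
                         distance = numeric(0)),
      caliper = NA_real_, n_treated = length(treated_idx),
      n_unmatched_treated = length(treated_idx)),
      class = "matched_sample"))
  }
  cal <- if (is.finite(caliper_sd_multiple))
    caliper_width(logit_ps, Z, caliper_sd_multiple, sd_type) else Inf
  ord <- switch(order,
    random = sample(length(treated_idx)),
    descending = base::order(logit_ps[treated_idx], decreasing = TRUE),
    data = seq_along(treated_idx))
  ti <- treated_idx[ord]
  lt <- logit_ps[ti]
  lc <- logit_ps[control_idx]
  res <- if (length(ti) * length(control_idx) <= 2e6)
    match_greedy_exact(lt, ti, lc, control_idx, cal)
  else
    match_greedy_fast(lt, ti, lc, control_idx, cal)
  pairs <- data.frame(treated = res$treated, control = res$control,
                      distance = res$distance)
  structure(list(pairs = pairs, caliper = cal,
                 n_treated = length(treated_idx),
                 n_unmatched_treated = length(treated_idx) - nrow(pairs)),
            class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("Matched sample: %d pairs (%d of %d treated matched), caliper %.4g\n",
              nrow(x$pairs), x$n_treated - x$n_unmatched_treated,
              x$n_treated, x$caliper))
  invisible(x)
}

#' Stratify subjects on quintiles of the propensity score
#'
#' Cut points are the 20th/40th/60th/80th empirical percentiles of the
#' full-sample propensity score distribution (linear interpolation of the
#' order statistics, `quantile` type 7). Subjects whose score equals a cut
#' point fall in the lower stratum.
#'
#' @param ps Propensity scores.
#' @return Object of class `stratum_assignment`: list with `stratum`
#'   (integer labels 1..5) and `cuts` (the four cut points).
#' @export
quintile_strata <- function(ps) {
  if (length(ps) < 5L) stop("need at least 5 subjects to form quintiles")
  cuts <- stats::quantile(ps, probs = c(0.2, 0.4, 0.6, 0.8), type = 7,
                          names = FALSE)
  stratum <- 1L + findInterval(ps, cuts, left.open = TRUE)
  structure(list(stratum = stratum, cuts = cuts),
            class = "stratum_assignment")
}

#' Inverse probability of treatment weights
#'
#' ATE weights: `z/e + (1-z)/(1-e)`, targeting the average treatment effect
#' in the whole population. ATT weights: `z + e(1-z)/(1-e)`, targeting the
#' average treatment effect in the treated (every treated subject has weight
#' 1). Raw weights are used; no truncation or stabilization.
#'
#' @param ps Propensity scores, strictly in (0, 1).
#' @param Z Treatment indicator (0/1).
#' @param estimand `"ATE"` or `"ATT"`.
#' @return Object of class `iptw_weights`: list with `w` and `estimand`.
#' @export
iptw_weights <- function(ps, Z, estimand = c("ATE", "ATT")) {
  estimand <- match.arg(estimand)
  Z <- as.integer(Z)
  stopifnot(length(Z) == length(ps))
  if (any(ps <= 0) || any(ps >= 1))
    stop("propensity scores must lie strictly between 0 and 1")
  w <- switch(estimand,
    ATE = Z / ps + (1 - Z) / (1 - ps),
    ATT = Z + ps * (1 - Z) / (1 - ps))
  structure(list(w = w, estimand = estimand), class = "iptw_weights")
}
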