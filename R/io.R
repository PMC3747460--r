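#' Read / write a scenario configuration
#'
#' Scenario configurations round-trip through JSON (or YAML when the `yaml`
#' package is available) with keys mirroring [scenario_config()]:
#' `n_subjects`, `prop_treated`, `target_marginal_hr`, `estimand`,
#' `n_reps`, `seed`.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_scenario_config`: a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the `yaml` package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  scenario_config(n_subjects = x$n_subjects,
                  prop_treated = x$prop_treated,
                  target_marginal_hr = x$target_marginal_hr,
                  estimand = x$estimand,
                  n_reps = x$n_reps,
                  seed = x$seed)
}

#' @rdname read_scenario_config
#' @param config A [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML configs requires the `yaml` package")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Tabulate conditioning designs by subject id
#'
#' Combines the outputs of the three propensity-score designs into one
#' per-subject table suitable for CSV export: matched-pair membership,
#' quintile stratum, and ATE/ATT weights.
#'
#' @param cohort Cohort data frame with an `id` column.
#' @param matched Optional `matched_sample`.
#' @param strata Optional `stratum_assignment`.
#' @param weights_ate,weights_att Optional `iptw_weights`.
#' @return Data frame with one row per subject: `id`, `z`, and a column per
#'   supplied design (`pair` is `NA` for unmatched subjects).
#' @export
design_table <- function(cohort, matched = NULL, strata = NULL,
                         weights_ate = NULL, weights_att = NULL) {
  out <- data.frame(id = cohort$id, z = cohort$z)
  n <- nrow(out)
  if (!is.null(matched)) {
    pair <- rep(NA_integer_, n)
    pair[matched$pairs$treated] <- seq_len(nrow(matched$pairs))
    pair[matched$pairs$control] <- seq_len(nrow(matched$pairs))
    out$pair <- pair
  }
  if (!is.null(strata)) out$stratum <- strata$stratum
  if (!is.null(weights_ate)) out$w_ate <- weights_ate$w
  if (!is.null(weights_att)) out$w_att <- weights_att$w
  out
}

#' Export per-replicate estimates as CSV
#'
#' One row per replicate and method: `rep`, `method`, `loghr`, `se`,
#' `ci_low`, `ci_high`, `converged`.
#'
#' @param estimates Data frame of effect estimates (e.g.
#'   `scenario_result$estimates` when run with `keep_estimates = TRUE`).
#' @param path File path.
#' @export
write_estimates_csv <- function(estimates, path) {
  utils::write.csv(as.data.frame(estimates), path, row.names = FALSE)
  invisible(path)
}
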