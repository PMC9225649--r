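# Sensitivity and scenario analysis: one-way (tornado), probabilistic with
# moment-matched distributions, acceptability curves, and the societal and
# reduced-compliance scenarios.

#' Default one-way sensitivity parameter set
#'
#' Every probability, utility, unit cost and adverse-event rate, varied
#' +/- 10% around its base value (probabilities clamped to [0, 1]); the two
#' discount rates are included as structural parameters. Callers may supply
#' their own bounds (e.g. 95% confidence limits) instead.
#'
#' @param cfg a `cua_config`
#' @return data frame with columns `path`, `base`, `low`, `high`,
#'   `bound_source`
#' @export
default_owsa_params <- function(cfg) {
  paths <- c(psa_distribution_specs(cfg)$path,
             "econ.discount_rate_costs", "econ.discount_rate_effects")
  base <- vapply(paths, function(p) cfg_get(cfg, p), numeric(1))
  is_prob <- grepl("response\\.|annual_p_|p_ineligible|p_postop|compliance|discount|male_fraction|^tree_utilities|^markov_utilities",
                   paths)
  low <- base * 0.9
  high <- ifelse(is_prob, pmin(1, base * 1.1), base * 1.1)
  data.frame(path = paths, base = base, low = low, high = high,
             bound_source = "plus_minus_10pct",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each parameter, re-runs the full model (tree, Markov, valuation,
#' incremental analysis) with only that parameter at its lower and then its
#' upper bound, restoring the base configuration between runs, and reports
#' the ICUR at each bound and the span between them, sorted descending.
#'
#' @param cfg a `cua_config`
#' @param params data frame as returned by [default_owsa_params()]
#' @return data frame of class `owsa_result`: `path`, `low`, `high`,
#'   `icur_low`, `icur_high`, `span`
#' @export
owsa <- function(cfg, params = default_owsa_params(cfg)) {
  if (!all(c("path", "low", "high") %in% names(params)))
    stopf("params must have columns path, low, high")
  lt <- resolve_life_table(cfg)
  run_icur <- function(c2) {
    r <- icur(run_arm(c2, "dupilumab", lt), run_arm(c2, "bsc", lt))
    if (is.na(r$icur)) r$delta_cost / r$delta_qaly else r$icur
  }
  n <- nrow(params)
  icur_low <- icur_high <- numeric(n)
  for (i in seq_len(n)) {
    icur_low[i] <- run_icur(cfg_set(cfg, params$path[i], params$low[i]))
    icur_high[i] <- run_icur(cfg_set(cfg, params$path[i], params$high[i]))
  }
  out <- data.frame(path = params$path, low = params$low, high = params$high,
                    icur_low = icur_low, icur_high = icur_high,
                    span = abs(icur_high - icur_low),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("owsa_result", "data.frame")
  out
}

# Moment-matching algebra ----------------------------------------------------

#' Moment-matched distribution parameters
#'
#' Gamma: `shape = (mean/se)^2`, `scale = se^2/mean`. Beta:
#' `alpha = mean * nu`, `beta = (1 - mean) * nu` with
#' `nu = mean (1 - mean) / se^2 - 1`; infeasible when
#' `se^2 >= mean (1 - mean)`.
#'
#' @param mean,se distribution mean and standard error
#' @return named list of family parameters
#' @export
gamma_moments <- function(mean, se) {
  if (mean <= 0) stopf("gamma mean must be positive")
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' @rdname gamma_moments
#' @export
beta_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stopf("beta mean must lie in (0, 1)")
  if (se^2 >= mean * (1 - mean))
    stopf("infeasible beta moments: se^2 = %g >= mean(1-mean) = %g",
          se^2, mean * (1 - mean))
  nu <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Sample a parameter from its assigned distribution
#'
#' Gamma for costs and resource use, beta for probabilities, proportions and
#' adverse-event incidence rates, normal truncated to [0, 1] for utilities,
#' all moment-matched to (mean, se). A zero standard error gives a
#' degenerate draw at the mean.
#'
#' @param spec list or one-row data frame with `family` in
#'   `c("gamma", "beta", "normal")`, `mean`, `se`
#' @param n number of draws
#' @return numeric vector of length `n`; consumes `n` uniforms from the
#'   current RNG stream regardless of family
#' @export
sample_parameter <- function(spec, n = 1) {
  m <- spec$mean; se <- spec$se
  if (se == 0) { stats::runif(n); return(rep(m, n)) }
  switch(spec$family,
    gamma = {
      p <- gamma_moments(m, se)
      stats::qgamma(stats::runif(n), shape = p$shape, scale = p$scale)
    },
    beta = {
      p <- beta_moments(m, se)
      stats::qbeta(stats::runif(n), p$alpha, p$beta)
    },
    normal = {
      lo <- stats::pnorm(0, m, se); hi <- stats::pnorm(1, m, se)
      stats::qnorm(lo + (hi - lo) * stats::runif(n), m, se)
    },
    stopf("unknown distribution family: %s", spec$family))
}

#' Distribution assignments for the probabilistic sensitivity analysis
#'
#' Builds the default parameter-uncertainty table: beta for probabilities,
#' proportions and adverse-event rates, gamma for unit costs and the drug
#' price, truncated normal for utilities; standard errors default to 10% of
#' the mean (the same rule as the one-way bounds) because the source
#' publication states distribution families but no standard errors.
#' Structurally fixed quantities (zero or unit probabilities, the BSC
#' acquisition cost, compliance, discount rates, the horizon and the
#' surgical age cutoff) are excluded.
#'
#' @param cfg a `cua_config`
#' @param se_fraction standard error as a fraction of the mean
#' @return data frame with columns `path`, `family`, `mean`, `se`
#' @export
psa_distribution_specs <- function(cfg, se_fraction = 0.10) {
  add <- function(path, family) {
    m <- cfg_get(cfg, path)
    data.frame(path = path, family = family, mean = m,
               se = se_fraction * m, stringsAsFactors = FALSE)
  }
  specs <- list()
  for (p in c("response.p_resp_wk24_dup", "response.p_resp_wk24_bsc",
              "response.p_resp_wk52_given_wk24_dup",
              "response.p_resp_wk52_given_wk24_bsc",
              "sustained_response.annual_p_sustain",
              "surgery_access.p_ineligible", "surgery_access.annual_p_surgery",
              "surgery_access.p_postop_to_uncontrolled"))
    specs[[length(specs) + 1L]] <- add(p, "beta")
  for (p in names(cfg$tree_utilities))
    specs[[length(specs) + 1L]] <- add(paste0("tree_utilities.", p), "normal")
  for (p in c("u_controlled", "u_inadequate", "u_surgery",
              "u_postop_controlled", "u_postop_uncontrolled"))
    specs[[length(specs) + 1L]] <- add(paste0("markov_utilities.", p), "normal")
  for (grp in c("responder", "nonresponder"))
    for (p in names(cfg$tree_costs[[grp]]))
      specs[[length(specs) + 1L]] <- add(paste0("tree_costs.", grp, ".", p), "gamma")
  for (p in c("controlled", "inadequate", "postop_controlled",
              "postop_uncontrolled"))
    specs[[length(specs) + 1L]] <- add(paste0("markov_state_costs.", p), "gamma")
  specs[[length(specs) + 1L]] <- add("drug_cost.price_per_administration", "gamma")
  for (p in c("ct_scan", "procedure", "annual_followup"))
    specs[[length(specs) + 1L]] <- add(paste0("surgery_costs.", p), "gamma")
  key <- snake_case(cfg$adverse_events$name)
  for (i in seq_along(key)) {
    for (col in c("rate_dup", "rate_bsc")) {
      if (cfg$adverse_events[[col]][i] > 0)
        specs[[length(specs) + 1L]] <-
          add(paste0("adverse_events.", key[i], ".", col), "beta")
    }
    specs[[length(specs) + 1L]] <-
      add(paste0("adverse_events.", key[i], ".unit_cost"), "gamma")
  }
  out <- do.call(rbind, specs)
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Jointly re-samples all uncertain parameters from their assigned
#' distributions and re-runs the full model for each draw, recording the
#' incremental cost and QALY pair. Infeasible distribution specifications
#' abort before any sampling; identical seeds give identical results.
#'
#' @param cfg a `cua_config`
#' @param n number of draws
#' @param seed integer seed for the single RNG stream
#' @param specs distribution table (default [psa_distribution_specs()])
#' @return object of class `psa_result`: `delta_cost`, `delta_qaly`
#'   (length-`n` vectors), the `n x p` matrix of sampled parameter values,
#'   the spec table, and the seed
#' @export
psa <- function(cfg, n = 1000, seed = cfg$seed, specs = psa_distribution_specs(cfg)) {
  if (n < 1) stopf("n must be at least 1")
  # fail on infeasible specs before drawing anything
  for (i in seq_len(nrow(specs))) {
    if (specs$se[i] == 0) next
    if (specs$family[i] == "beta") beta_moments(specs$mean[i], specs$se[i])
    if (specs$family[i] == "gamma") gamma_moments(specs$mean[i], specs$se[i])
  }
  set.seed(seed)
  draws <- matrix(NA_real_, n, nrow(specs),
                  dimnames = list(NULL, specs$path))
  for (j in seq_len(nrow(specs)))
    draws[, j] <- sample_parameter(specs[j, ], n)
  lt <- resolve_life_table(cfg)
  dc <- dq <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cfg
    for (j in seq_len(nrow(specs)))
      ci <- cfg_set(ci, specs$path[j], unname(draws[i, j]))
    r <- icur(run_arm(ci, "dupilumab", lt), run_arm(ci, "bsc", lt))
    dc[i] <- r$delta_cost; dq[i] <- r$delta_qaly
  }
  structure(list(seed = seed, n = n, draws = draws, specs = specs,
                 delta_cost = dc, delta_qaly = dq),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d), %d sampled parameters\n",
              x$n, x$seed, ncol(x$draws)))
  cat(sprintf("Mean incremental cost EUR %.0f, mean incremental QALYs %.3f\n",
              mean(x$delta_cost), mean(x$delta_qaly)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the fraction of PSA draws whose
#' incremental net monetary benefit is non-negative.
#'
#' @param psa a `psa_result`
#' @param wtp_grid thresholds in EUR/QALY
#' @return data frame with columns `wtp`, `probability`
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0L) stopf("wtp_grid must be non-empty")
  prob <- vapply(wtp_grid,
                 function(l) mean(l * psa$delta_qaly - psa$delta_cost >= 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Scenario: societal perspective
#'
#' Returns a configuration identical to the input except that the costing
#' perspective is societal, so productivity losses (workdays lost per state
#' times 8 hours times EUR 29.80/h under the defaults) accrue as indirect
#' costs.
#'
#' @param cfg a `cua_config`
#' @return modified `cua_config`
#' @export
scenario_societal <- function(cfg) {
  if (is.null(cfg$indirect) || is.null(cfg$indirect$workdays_lost_per_year_by_state))
    stopf("societal scenario requires workdays lost per health state")
  cfg$econ$perspective <- "societal"
  cfg
}

#' Scenario: reduced compliance
#'
#' Returns a configuration with the dupilumab compliance rate replaced
#' (base case 100%; the published alternative scenario uses 96.95%).
#' Compliance scales only drug acquisition; efficacy is untouched.
#'
#' @param cfg a `cua_config`
#' @param rate compliance in (0, 1]
#' @return modified `cua_config`
#' @export
scenario_compliance <- function(cfg, rate = 0.9695) {
  if (rate <= 0 || rate > 1) stopf("compliance rate must lie in (0, 1]")
  cfg$drug_cost$compliance <- rate
  cfg
}
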