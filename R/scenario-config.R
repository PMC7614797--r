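#' Define one simulation scenario
#'
#' A scenario bundles every generative and analysis parameter needed to
#' simulate one cell of the study grid: the trial size, the prevalence of the
#' binary stratification covariate, the coefficients of the outcome model
#' \deqn{Y_i = \alpha + \beta_T T_i + \beta_X X_i + \beta_{TX} T_i X_i + e_i,
#' \quad e_i \sim N(0,1),}
#' the misclassification ("stratification error") process, the error-discovery
#' process, and the replication settings.
#'
#' @param n_participants Total trial sample size (default 1000).
#' @param covariate_prevalence Prevalence \eqn{\pi} of the binary covariate
#'   \eqn{X} (default 0.5).
#' @param alpha_coef Intercept \eqn{\alpha} of the outcome model.
#' @param beta_t Main treatment effect \eqn{\beta_T}.
#' @param beta_x Covariate effect \eqn{\beta_X} (in residual-SD units).
#' @param beta_tx Treatment-by-covariate interaction \eqn{\beta_{TX}}.
#' @param error_rate Overall probability that a participant's stratification
#'   covariate is misclassified at randomisation.
#' @param error_pattern `"equal"` for a common error rate in both strata, or
#'   `"unequal_3x"` for a rate three times higher in one stratum while
#'   preserving `error_rate` overall (see [stratum_error_rates()]).
#' @param discovery_rate Overall probability that a stratification error is
#'   discovered before analysis (ignored when `discovery_pattern = "all"`).
#' @param discovery_pattern `"all"` (every error discovered, so the updated
#'   strata equal the true strata), `"equal"` (each error discovered with
#'   probability `discovery_rate` in both arms), or
#'   `"unequal_3x_intervention"` (discovery three times more likely in the
#'   intervention arm, preserving `discovery_rate` overall under 1:1
#'   allocation).
#' @param block_size Permuted-block length used within each randomisation
#'   stratum; must be a positive even integer (default 4).
#' @param n_reps Number of simulation repetitions the scenario requests.
#' @param seed Optional integer seed associated with the scenario.
#' @param scenario_id Optional identifier; a descriptive one is generated
#'   when omitted.
#'
#' @return An object of class `scenario_config`: a named list of validated
#'   parameters.
#'
#' @examples
#' cfg <- scenario_config(beta_t = 0.2, beta_x = 3,
#'                        error_rate = 0.2, error_pattern = "equal")
#' cfg
#' @seealso [simulate_trial()], [scenario_grid()]
#' @export
scenario_config <- function(n_participants = 1000L,
                            covariate_prevalence = 0.5,
                            alpha_coef = 0,
                            beta_t = 0,
                            beta_x = 1,
                            beta_tx = 0,
                            error_rate = 0,
                            error_pattern = c("equal", "unequal_3x"),
                            discovery_rate = 1,
                            discovery_pattern = c("all", "equal",
                                                  "unequal_3x_intervention"),
                            block_size = 4L,
                            n_reps = 10000L,
                            seed = NULL,
                            scenario_id = NULL) {
  error_pattern <- match.arg(error_pattern)
  discovery_pattern <- match.arg(discovery_pattern)

  check_count(n_participants, "n_participants")
  check_count(block_size, "block_size")
  check_count(n_reps, "n_reps")
  check_prob(covariate_prevalence, "covariate_prevalence")
  check_prob(error_rate, "error_rate")
  check_prob(discovery_rate, "discovery_rate")
  for (nm in c("alpha_coef", "beta_t", "beta_x", "beta_tx")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (block_size %% 2L != 0L) {
    stop("`block_size` must be a positive even integer", call. = FALSE)
  }
  if (n_participants < block_size) {
    stop("`n_participants` must be at least `block_size`", call. = FALSE)
  }

  # fail fast on infeasible derived rates
  stratum_error_rates(error_rate, error_pattern, covariate_prevalence)
  arm_discovery_rates(discovery_rate, discovery_pattern)

  cfg <- structure(
    list(n_participants = as.integer(n_participants),
         covariate_prevalence = covariate_prevalence,
         alpha_coef = alpha_coef,
         beta_t = beta_t,
         beta_x = beta_x,
         beta_tx = beta_tx,
         error_rate = error_rate,
         error_pattern = error_pattern,
         discovery_rate = discovery_rate,
         discovery_pattern = discovery_pattern,
         block_size = as.integer(block_size),
         n_reps = as.integer(n_reps),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "scenario_config")
  cfg$scenario_id <- if (is.null(scenario_id)) default_scenario_id(cfg) else
    as.character(scenario_id)
  cfg
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer", name),
         call. = FALSE)
  }
  invisible(x)
}

default_scenario_id <- function(cfg) {
  paste0("n", cfg$n_participants,
         "_pi", cfg$covariate_prevalence,
         "_bT", cfg$beta_t, "_bX", cfg$beta_x, "_bTX", cfg$beta_tx,
         "_err", cfg$error_rate, "-", cfg$error_pattern,
         "_disc", if (cfg$discovery_pattern == "all") "all" else
           paste0(cfg$discovery_rate, "-", cfg$discovery_pattern))
}

#' Stratum-specific misclassification probabilities
#'
#' Converts an overall stratification error rate into per-stratum flip
#' probabilities `(p0, p1)` for strata `X = 0` and `X = 1`.
#'
#' Under `pattern = "equal"` both strata share the overall rate. Under
#' `pattern = "unequal_3x"` the rate is three times higher in one stratum
#' while the marginal rate is preserved:
#' \eqn{(1-\pi) p_0 + \pi p_1 = } `error_rate` with the higher rate assigned
#' to the more common stratum (stratum `X = 1` when the prevalence is 0.5,
#' matching the convention that errors are three times more likely in the
#' `X = 1` stratum, e.g. rates 0.1 and 0.3 for a 20% overall rate).
#'
#' @param error_rate Overall misclassification probability.
#' @param pattern `"equal"` or `"unequal_3x"`.
#' @param prevalence Prevalence of stratum `X = 1`.
#' @return Named numeric vector `c(p0 = , p1 = )`.
#' @examples
#' stratum_error_rates(0.2, "unequal_3x", 0.5)   # 0.1 and 0.3
#' stratum_error_rates(0.2, "unequal_3x", 0.75)  # 0.08 and 0.24
#' @export
stratum_error_rates <- function(error_rate, pattern = c("equal", "unequal_3x"),
                                prevalence = 0.5) {
  pattern <- match.arg(pattern)
  check_prob(error_rate, "error_rate")
  check_prob(prevalence, "prevalence")
  if (pattern == "equal") {
    rates <- c(p0 = error_rate, p1 = error_rate)
  } else {
    high <- if (prevalence >= 0.5) 1L else 0L
    p_high <- prevalence * (high == 1L) + (1 - prevalence) * (high == 0L)
    p_low_stratum <- 1 - p_high
    # rate = P(low stratum) * p_low + P(high stratum) * 3 p_low
    p_low <- error_rate / (p_low_stratum + 3 * p_high)
    rates <- if (high == 1L) c(p0 = p_low, p1 = 3 * p_low) else
      c(p0 = 3 * p_low, p1 = p_low)
  }
  if (any(rates > 1)) {
    stop(sprintf(paste0("infeasible scenario: derived stratum error rates ",
                        "(%.3f, %.3f) exceed 1"), rates[1], rates[2]),
         call. = FALSE)
  }
  rates
}

#' Arm-specific error-discovery probabilities
#'
#' Converts an overall discovery rate into per-arm probabilities
#' `(d0, d1)` that a stratification error is discovered in the control and
#' intervention arms. `"equal"` uses the overall rate in both arms; `"all"`
#' discovers every error; `"unequal_3x_intervention"` makes discovery three
#' times more likely in the intervention arm while preserving the overall
#' rate under 1:1 allocation, i.e. `(d0, d1) = (rate/2, 3*rate/2)` (0.25 and
#' 0.75 for a 50% overall rate).
#'
#' @param discovery_rate Overall probability of discovering an error.
#' @param pattern `"all"`, `"equal"` or `"unequal_3x_intervention"`.
#' @return Named numeric vector `c(d0 = , d1 = )`.
#' @export
arm_discovery_rates <- function(discovery_rate,
                                pattern = c("all", "equal",
                                            "unequal_3x_intervention")) {
  pattern <- match.arg(pattern)
  check_prob(discovery_rate, "discovery_rate")
  rates <- switch(pattern,
    all = c(d0 = 1, d1 = 1),
    equal = c(d0 = discovery_rate, d1 = discovery_rate),
    unequal_3x_intervention = c(d0 = discovery_rate / 2,
                                d1 = 3 * discovery_rate / 2))
  if (any(rates > 1)) {
    stop(sprintf(paste0("infeasible scenario: derived arm discovery rates ",
                        "(%.3f, %.3f) exceed 1"), rates[1], rates[2]),
         call. = FALSE)
  }
  rates
}

#' True value of the marginal treatment effect
#'
#' The marginal (average across strata) treatment effect implied by the
#' outcome model is \eqn{\beta_T + \pi \beta_{TX}}. This is the estimand of
#' a main-effects analysis that omits the interaction term.
#'
#' @param config A [scenario_config()].
#' @return A single number.
#' @export
true_marginal_effect <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  config$beta_t + config$covariate_prevalence * config$beta_tx
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$scenario_id, "\n", sep = "")
  cat(sprintf("  n = %d, prevalence = %g, block size = %d\n",
              x$n_participants, x$covariate_prevalence, x$block_size))
  cat(sprintf("  outcome model: alpha = %g, beta_T = %g, beta_X = %g, beta_TX = %g\n",
              x$alpha_coef, x$beta_t, x$beta_x, x$beta_tx))
  er <- stratum_error_rates(x$error_rate, x$error_pattern,
                            x$covariate_prevalence)
  cat(sprintf("  errors: %g overall (%s; stratum rates %g / %g)\n",
              x$error_rate, x$error_pattern, er[1], er[2]))
  dr <- arm_discovery_rates(x$discovery_rate, x$discovery_pattern)
  cat(sprintf("  discovery: %s (arm rates %g / %g)\n",
              x$discovery_pattern, dr[1], dr[2]))
  cat(sprintf("  replication: n_reps = %d%s\n", x$n_reps,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Read or write a scenario configuration file
#'
#' Scenario configurations are stored as plain-text YAML key-value files so
#' that study settings can be version-controlled and passed to the
#' command-line driver. Unknown keys are rejected.
#'
#' @param path File path.
#' @param config A [scenario_config()] (for writing).
#' @return `read_scenario_config()` returns a [scenario_config()];
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(scenario_config)), "")
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0L) {
    stop("unknown scenario fields in config file: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(scenario_config, vals)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
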