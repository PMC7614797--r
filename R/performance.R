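#' Summarise simulation repetitions into performance measures
#'
#' Computes the standard simulation-study performance measures for one
#' (scenario, method, parameter) cell, together with a Monte Carlo standard
#' error (MCSE) for each:
#' \itemize{
#'   \item bias: \eqn{\bar\beta - \beta_{true}}; MCSE \eqn{EmpSE/\sqrt{R}}.
#'   \item empirical SE: \eqn{\sqrt{\sum_j(\hat\beta_j-\bar\beta)^2/(R-1)}};
#'     MCSE \eqn{EmpSE/\sqrt{2(R-1)}}.
#'   \item model-based SE: \eqn{\sqrt{\frac1R\sum_j \widehat{Var}(\hat\beta_j)}};
#'     MCSE \eqn{\sqrt{Var(\widehat{Var})/(4 R\, ModSE^2)}}.
#'   \item relative \% error in the model SE: \eqn{100(ModSE/EmpSE - 1)};
#'     MCSE by the delta method, combining the ModSE and EmpSE MCSEs.
#'   \item coverage and rejection percentages, with binomial MCSE
#'     \eqn{100\sqrt{\hat p(1-\hat p)/R}}.
#' }
#' When the empirical SE is zero but the model SE is not, the relative error
#' is undefined and reported as `NA` with a warning.
#'
#' @param estimates Numeric vector of parameter estimates, one per
#'   repetition.
#' @param variances Numeric vector of model-based variance estimates
#'   \eqn{\widehat{Var}(\hat\beta_j)} (squared model SEs).
#' @param rejected Logical vector: null hypothesis rejected at the nominal
#'   level.
#' @param covered Logical vector: confidence interval contained the true
#'   value.
#' @param true_value The true parameter value the estimates target.
#' @return A one-row data frame with columns `n_reps_used`, `bias`,
#'   `emp_se`, `mod_se`, `rel_err_pct`, `coverage_pct`, `rejection_pct` and
#'   MCSE columns `mcse_bias`, `mcse_emp_se`, `mcse_mod_se`, `mcse_rel_err`,
#'   `mcse_coverage`, `mcse_rejection`.
#' @examples
#' summarise_performance(c(0.1, 0.2, 0.3), c(0.01, 0.01, 0.01),
#'                       rejected = c(FALSE, TRUE, TRUE),
#'                       covered = c(TRUE, TRUE, TRUE), true_value = 0.2)
#' @export
summarise_performance <- function(estimates, variances, rejected, covered,
                                  true_value) {
  R <- length(estimates)
  if (R < 2L) stop("need at least 2 repetitions", call. = FALSE)
  if (length(variances) != R || length(rejected) != R ||
      length(covered) != R) {
    stop("all repetition vectors must have the same length", call. = FALSE)
  }
  if (any(variances < 0)) stop("`variances` must be non-negative",
                               call. = FALSE)

  mean_est <- mean(estimates)
  bias <- mean_est - true_value
  emp_se <- stats::sd(estimates)
  mod_se <- sqrt(mean(variances))
  p_cov <- mean(covered)
  p_rej <- mean(rejected)

  mcse_bias <- emp_se / sqrt(R)
  mcse_emp_se <- emp_se / sqrt(2 * (R - 1))
  mcse_mod_se <- if (mod_se > 0) {
    sqrt(stats::var(variances) / (4 * R * mod_se^2))
  } else 0

  if (emp_se > 0) {
    rel_err <- 100 * (mod_se / emp_se - 1)
    mcse_rel_err <- 100 * (mod_se / emp_se) *
      sqrt(mcse_mod_se^2 / mod_se^2 + mcse_emp_se^2 / emp_se^2)
  } else if (mod_se > 0) {
    warning("empirical SE is zero; relative error in the model SE is ",
            "undefined and reported as NA")
    rel_err <- NA_real_
    mcse_rel_err <- NA_real_
  } else {
    rel_err <- NA_real_
    mcse_rel_err <- NA_real_
  }

  data.frame(n_reps_used = R,
             bias = bias,
             emp_se = emp_se,
             mod_se = mod_se,
             rel_err_pct = rel_err,
             coverage_pct = 100 * p_cov,
             rejection_pct = 100 * p_rej,
             mcse_bias = mcse_bias,
             mcse_emp_se = mcse_emp_se,
             mcse_mod_se = mcse_mod_se,
             mcse_rel_err = mcse_rel_err,
             mcse_coverage = 100 * sqrt(p_cov * (1 - p_cov) / R),
             mcse_rejection = 100 * sqrt(p_rej * (1 - p_rej) / R))
}

#' Correlation between arm sample means across repetitions
#'
#' Stratified randomisation induces a positive correlation between the
#' control-arm and intervention-arm sample mean outcomes across repeated
#' trials; an unadjusted analysis ignores this correlation, which is why it
#' is conservative. This function estimates that correlation from the
#' per-repetition arm means and reports the Monte Carlo SE of its Fisher
#' z-transformation, \eqn{1/\sqrt{R-3}}.
#'
#' @param mean_control,mean_intervention Numeric vectors of arm sample
#'   means, one entry per repetition.
#' @return A list with `correlation`, `fisher_z_mcse` and `n_reps`.
#' @export
arm_mean_correlation <- function(mean_control, mean_intervention) {
  R <- length(mean_control)
  if (length(mean_intervention) != R) {
    stop("arm-mean vectors must have the same length", call. = FALSE)
  }
  if (R < 4L) stop("need at least 4 repetitions", call. = FALSE)
  if (stats::sd(mean_control) == 0 || stats::sd(mean_intervention) == 0) {
    warning("zero variance in an arm-mean series; correlation undefined")
    rho <- NA_real_
  } else {
    rho <- stats::cor(mean_control, mean_intervention)
  }
  list(correlation = rho,
       fisher_z_mcse = 1 / sqrt(R - 3),
       n_reps = R)
}

#' Analytic power of the two-sample t-test
#'
#' Exact power (via the noncentral t distribution) of the two-sided
#' two-sample t-test for a difference in means `delta` with common SD `sd`
#' and `n_per_arm` participants per arm. Used as a design check: the main
#' study design (500 per arm, `delta` 0.2 SD) has 88% power at the 5% level.
#'
#' @param n_per_arm Participants per arm.
#' @param delta True difference in means.
#' @param sd Common outcome standard deviation.
#' @param alpha Two-sided significance level.
#' @return Power as a probability.
#' @examples
#' power_two_sample_t(500, 0.2, 1, 0.05)  # ~0.88
#' @export
power_two_sample_t <- function(n_per_arm, delta, sd = 1, alpha = 0.05) {
  if (n_per_arm < 2) stop("`n_per_arm` must be at least 2", call. = FALSE)
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  check_prob(alpha, "alpha")
  se <- sd * sqrt(2 / n_per_arm)
  df <- 2 * (n_per_arm - 1)
  ncp <- delta / se
  tcrit <- stats::qt(1 - alpha / 2, df)
  # both rejection tails, so power equals alpha exactly under the null
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Analytic power of the interaction test in a balanced 2x2 design
#'
#' Power of the two-sided test of the treatment-by-stratum interaction
#' contrast in a balanced two-way layout with `n_per_cell` observations per
#' cell. The interaction estimate has standard error
#' \eqn{sd\sqrt{4/n_{cell}}}, so the noncentrality parameter is
#' \eqn{\beta_{TX}/(sd\sqrt{4/n_{cell}})} with \eqn{4(n_{cell}-1)} error
#' degrees of freedom. The study's interaction designs (250 per cell,
#' interaction 0.2 or 0.4 SD) have 35% and 88% power.
#'
#' @param n_per_cell Observations per (arm x stratum) cell.
#' @param beta_tx True interaction effect.
#' @param sd Residual standard deviation.
#' @param alpha Two-sided significance level.
#' @return Power as a probability.
#' @examples
#' power_interaction(250, 0.2)  # ~0.35
#' power_interaction(250, 0.4)  # ~0.88
#' @export
power_interaction <- function(n_per_cell, beta_tx, sd = 1, alpha = 0.05) {
  if (n_per_cell < 2) stop("`n_per_cell` must be at least 2", call. = FALSE)
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  check_prob(alpha, "alpha")
  se <- sd * sqrt(4 / n_per_cell)
  df <- 4 * (n_per_cell - 1)
  ncp <- beta_tx / se
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}
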