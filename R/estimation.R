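#' Ordinary least squares with classical inference
#'
#' Fits \eqn{Y = D\beta + e} by OLS and returns coefficient-level inference
#' using the classical model-based variance
#' \eqn{\hat\sigma^2 (D'D)^{-1}} with \eqn{\hat\sigma^2 = RSS/(n-p)}.
#' Confidence intervals and the two-sided test of zero use the same
#' t critical value with \eqn{n-p} degrees of freedom, so `reject` is `TRUE`
#' exactly when the interval excludes zero.
#'
#' @param y Numeric response vector.
#' @param design Numeric design matrix (include the intercept column
#'   yourself); column names label the output.
#' @param conf_level Confidence level (default 0.95); the test size is
#'   `1 - conf_level`.
#' @return A data frame with one row per coefficient and columns `term`,
#'   `estimate`, `model_se`, `ci_low`, `ci_high`, `reject`, `df`.
#' @examples
#' y <- c(1, 2, 3, 4)
#' D <- cbind(intercept = 1, treatment = c(0, 0, 1, 1))
#' fit_ols(y, D)  # treatment estimate 2, SE sqrt(0.5)
#' @export
fit_ols <- function(y, design, conf_level = 0.95) {
  design <- as.matrix(design)
  n <- length(y)
  p <- ncol(design)
  if (nrow(design) != n) {
    stop("`y` and `design` must have the same number of rows", call. = FALSE)
  }
  if (n <= p) {
    stop("need more observations than design columns", call. = FALSE)
  }
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(p))
  }
  qrd <- qr(design)
  if (qrd$rank < p) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):p]]
    stop("singular design: column(s) ", paste(dropped, collapse = ", "),
         " are collinear or constant", call. = FALSE)
  }
  est <- qr.coef(qrd, y)
  res <- y - design %*% est
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qrd))[order(qrd$pivot), order(qrd$pivot),
                                 drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  ci_low <- est - tcrit * se
  ci_high <- est + tcrit * se
  data.frame(term = colnames(design),
             estimate = as.numeric(est),
             model_se = se,
             ci_low = ci_low,
             ci_high = ci_high,
             reject = ci_low > 0 | ci_high < 0,
             df = df,
             row.names = NULL)
}

adjustment_column <- function(trial, adjustment) {
  switch(adjustment,
         none = NULL,
         randomisation_Z = trial$z_rand,
         true_X = trial$x_true,
         updated_W = trial$w_updated,
         stop("unknown adjustment `", adjustment, "`", call. = FALSE))
}

fit_result_row <- function(fit, term, parameter, adjustment,
                           includes_interaction) {
  i <- match(term, fit$term)
  data.frame(parameter = parameter,
             adjustment = adjustment,
             includes_interaction = includes_interaction,
             estimate = fit$estimate[i],
             model_se = fit$model_se[i],
             ci_low = fit$ci_low[i],
             ci_high = fit$ci_high[i],
             reject_5pct = fit$reject[i],
             row.names = NULL)
}

#' Estimate the treatment effect under a chosen covariate adjustment
#'
#' Fits a linear regression of the outcome on treatment plus, optionally,
#' one stratum covariate: none (unadjusted), the randomisation strata `Z`,
#' the true strata `X`, or the updated strata `W`. The treatment coefficient
#' targets the marginal treatment effect \eqn{E[Y(1) - Y(0)]}, whose true
#' value under the generating model is \eqn{\beta_T + \pi\beta_{TX}}
#' ([true_marginal_effect()]); when the generating interaction is zero this
#' is simply \eqn{\beta_T}.
#'
#' @param trial A `trial_data` data frame from [simulate_trial()].
#' @param adjustment One of `"none"`, `"randomisation_Z"`, `"true_X"`,
#'   `"updated_W"`.
#' @param conf_level Confidence level for the interval and test.
#' @return A one-row data frame (a fit result) with columns `parameter`
#'   (`"treatment"`), `adjustment`, `includes_interaction`, `estimate`,
#'   `model_se`, `ci_low`, `ci_high`, `reject_5pct`.
#' @export
analyse_treatment_effect <- function(trial,
                                     adjustment = c("none", "randomisation_Z",
                                                    "true_X", "updated_W"),
                                     conf_level = 0.95) {
  stopifnot(inherits(trial, "trial_data"))
  adjustment <- match.arg(adjustment)
  design <- cbind(intercept = 1, treatment = trial$t_arm)
  covar <- adjustment_column(trial, adjustment)
  if (!is.null(covar)) {
    design <- cbind(design, stratum = covar)
  }
  fit <- fit_ols(trial$y, design, conf_level)
  fit_result_row(fit, "treatment", "treatment", adjustment,
                 includes_interaction = FALSE)
}

#' Estimate treatment and treatment-by-stratum interaction effects
#'
#' Fits a linear regression of the outcome on treatment, one stratum
#' covariate `C` (the randomisation, true or updated strata) and their
#' product. The interaction coefficient targets
#' \eqn{E[Y(1)-Y(0) \mid X = 1] - E[Y(1)-Y(0) \mid X = 0]}, with true value
#' \eqn{\beta_{TX}}. Because the covariate enters as a 0/1 indicator, the
#' treatment coefficient is the subgroup treatment effect in stratum
#' `C = 0` (true value \eqn{\beta_T}).
#'
#' @param trial A `trial_data` data frame.
#' @param covariate Which stratum variable defines the subgroups:
#'   `"randomisation_Z"`, `"true_X"` or `"updated_W"`.
#' @param conf_level Confidence level for intervals and tests.
#' @return A two-row data frame of fit results (`parameter` equal to
#'   `"treatment"` and `"interaction"`), with the same columns as
#'   [analyse_treatment_effect()].
#' @export
analyse_interaction <- function(trial,
                                covariate = c("randomisation_Z", "true_X",
                                              "updated_W"),
                                conf_level = 0.95) {
  stopifnot(inherits(trial, "trial_data"))
  covariate <- match.arg(covariate)
  cvar <- adjustment_column(trial, covariate)
  design <- cbind(intercept = 1,
                  treatment = trial$t_arm,
                  stratum = cvar,
                  treatment_x_stratum = trial$t_arm * cvar)
  fit <- fit_ols(trial$y, design, conf_level)
  rbind(fit_result_row(fit, "treatment", "treatment", covariate,
                       includes_interaction = TRUE),
        fit_result_row(fit, "treatment_x_stratum", "interaction", covariate,
                       includes_interaction = TRUE))
}

#' Marginal treatment effect ignoring an underlying interaction
#'
#' Convenience wrapper around [analyse_treatment_effect()] for the setting
#' where the data were generated with a treatment-by-covariate interaction
#' but the analysis model omits the interaction term, as is usual for primary
#' trial analyses. The model is identical to [analyse_treatment_effect()];
#' the distinction is the estimand: performance must be judged against
#' [true_marginal_effect()], not \eqn{\beta_T}.
#'
#' @inheritParams analyse_treatment_effect
#' @return A one-row data frame of fit results.
#' @export
analyse_marginal_ignoring_interaction <- function(trial,
    adjustment = c("none", "randomisation_Z", "true_X", "updated_W"),
    conf_level = 0.95) {
  analyse_treatment_effect(trial, adjustment, conf_level)
}
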