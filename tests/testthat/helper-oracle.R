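# Brute-force OLS oracle: explicit normal equations, independent of the
# QR-based implementation under test.
ols_oracle <- function(y, X, conf_level = 0.95) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- unname(sqrt(diag(solve(XtX)) * sigma2))
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  list(estimate = as.numeric(beta), se = as.numeric(se),
       ci_low = as.numeric(beta) - tcrit * se,
       ci_high = as.numeric(beta) + tcrit * se)
}

# Closed-form cell means of the outcome model for a config.
cell_mean <- function(config, t, x) {
  config$alpha_coef + config$beta_t * t + config$beta_x * x +
    config$beta_tx * t * x
}

# Maximum running within-stratum arm imbalance over the enrollment sequence.
max_prefix_imbalance <- function(trial) {
  worst <- 0L
  for (s in 0:1) {
    arm <- trial$t_arm[trial$z_rand == s]
    if (length(arm) == 0L) next
    running <- cumsum(ifelse(arm == 1L, 1L, -1L))
    worst <- max(worst, max(abs(running)))
  }
  worst
}
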