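#' Generate the true stratification covariate
#'
#' Draws the binary baseline covariate \eqn{X_i} for `n` participants as
#' independent Bernoulli(`prevalence`) variables. This is the covariate that
#' drives the outcome model; the randomisation may see a misclassified copy
#' of it (see [apply_misclassification()]).
#'
#' @param n Number of participants.
#' @param prevalence Probability that \eqn{X_i = 1}.
#' @return Integer vector of 0/1 values of length `n`.
#' @export
generate_true_covariates <- function(n, prevalence = 0.5) {
  check_count(n, "n")
  check_prob(prevalence, "prevalence")
  as.integer(stats::runif(n) < prevalence)
}

#' Misclassify the stratification covariate
#'
#' Flips each participant's covariate independently with a stratum-specific
#' probability, producing the randomisation stratum \eqn{Z_i} actually used
#' to allocate treatment. Misclassification happens before treatment
#' allocation and is therefore independent of the (future) arm.
#'
#' @param x_true 0/1 vector of true covariate values.
#' @inheritParams stratum_error_rates
#' @return A list with components `z_rand` (0/1 vector) and `is_error`
#'   (logical vector, `TRUE` where `z_rand != x_true`).
#' @seealso [stratum_error_rates()] for the per-stratum rates.
#' @export
apply_misclassification <- function(x_true, error_rate,
                                    pattern = c("equal", "unequal_3x"),
                                    prevalence = 0.5) {
  pattern <- match.arg(pattern)
  rates <- stratum_error_rates(error_rate, pattern, prevalence)
  p_flip <- ifelse(x_true == 1L, rates[["p1"]], rates[["p0"]])
  flip <- stats::runif(length(x_true)) < p_flip
  z <- ifelse(flip, 1L - x_true, x_true)
  list(z_rand = as.integer(z), is_error = flip)
}

#' Stratified permuted-block randomisation
#'
#' Assigns participants 1:1 to control (0) or intervention (1) using randomly
#' permuted blocks within each randomisation stratum. Participants are taken
#' in enrollment (index) order within their stratum; each block is an
#' independent uniformly random permutation of `block_size/2` zeros and ones,
#' and the final block in a stratum may be left incomplete. Within-stratum
#' arm imbalance therefore never exceeds `block_size/2` at any point of the
#' enrollment sequence.
#'
#' @param z_rand 0/1 vector of randomisation strata.
#' @param block_size Positive even block length (default 4).
#' @return Integer 0/1 vector of treatment assignments.
#' @export
stratified_block_randomise <- function(z_rand, block_size = 4L) {
  check_count(block_size, "block_size")
  if (block_size %% 2L != 0L) {
    stop("`block_size` must be a positive even integer", call. = FALSE)
  }
  half <- block_size %/% 2L
  t_arm <- integer(length(z_rand))
  for (s in c(0L, 1L)) {
    idx <- which(z_rand == s)
    m <- length(idx)
    if (m == 0L) next  # degenerate stratum: nothing to assign
    n_blocks <- ceiling(m / block_size)
    u <- stats::runif(n_blocks * block_size)
    block_id <- rep(seq_len(n_blocks), each = block_size)
    # ranking the uniforms within each block yields a uniform permutation
    seq_assign <- integer(n_blocks * block_size)
    seq_assign[order(block_id, u)] <-
      rep(c(rep(1L, half), rep(0L, half)), n_blocks)
    t_arm[idx] <- seq_assign[seq_len(m)]
  }
  t_arm
}

#' Discover stratification errors and form the updated strata
#'
#' After randomisation, each stratification error is discovered independently
#' with an arm-specific probability. The updated stratum \eqn{W_i} equals the
#' true stratum where no error occurred or the error was discovered, and the
#' (incorrect) randomisation stratum where an error remains undiscovered.
#' Participants whose covariate was recorded correctly are never altered.
#'
#' @param is_error Logical vector flagging misclassified participants.
#' @param t_arm 0/1 treatment assignments (discovery may depend on arm).
#' @param x_true,z_rand 0/1 vectors of true and randomisation strata.
#' @inheritParams arm_discovery_rates
#' @return A list with components `w_updated` (0/1 vector) and
#'   `is_discovered` (logical; `TRUE` only for discovered errors).
#' @export
apply_discovery <- function(is_error, t_arm, discovery_rate,
                            pattern = c("all", "equal",
                                        "unequal_3x_intervention"),
                            x_true, z_rand) {
  pattern <- match.arg(pattern)
  rates <- arm_discovery_rates(discovery_rate, pattern)
  d <- ifelse(t_arm == 1L, rates[["d1"]], rates[["d0"]])
  is_discovered <- is_error & (stats::runif(length(is_error)) < d)
  w <- ifelse(is_error & !is_discovered, z_rand, x_true)
  list(w_updated = as.integer(w), is_discovered = is_discovered)
}

#' Generate continuous outcomes from the linear model
#'
#' Outcomes follow
#' \eqn{Y_i = \alpha + \beta_T T_i + \beta_X X_i + \beta_{TX} T_i X_i + e_i}
#' with independent standard-normal residuals. Outcomes depend on the TRUE
#' covariate only; the misclassified and updated strata never enter the
#' data-generating model.
#'
#' @param x_true 0/1 true covariate values.
#' @param t_arm 0/1 treatment assignments.
#' @param config A [scenario_config()] supplying the coefficients.
#' @return Numeric outcome vector.
#' @export
generate_outcomes <- function(x_true, t_arm, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(x_true) != length(t_arm)) {
    stop("`x_true` and `t_arm` must have the same length", call. = FALSE)
  }
  config$alpha_coef + config$beta_t * t_arm + config$beta_x * x_true +
    config$beta_tx * t_arm * x_true + stats::rnorm(length(x_true))
}

#' Simulate one complete trial
#'
#' Composes the generators in the order the processes occur in a real trial:
#' true covariate, misclassification at randomisation, stratified
#' permuted-block allocation within the (possibly wrong) strata, error
#' discovery, and finally outcomes from the linear model.
#'
#' @param config A [scenario_config()].
#' @param seed Optional integer; when supplied (or stored in `config`) the
#'   RNG is seeded so the trial is exactly reproducible.
#' @return A `trial_data` data frame with one row per participant and columns
#'   `id`, `x_true`, `z_rand`, `t_arm`, `w_updated`, `y`, `is_error`,
#'   `is_discovered`.
#' @examples
#' trial <- simulate_trial(scenario_config(error_rate = 0.2, beta_x = 3,
#'                                         discovery_pattern = "equal",
#'                                         discovery_rate = 0.5), seed = 1)
#' head(trial)
#' table(z = trial$z_rand, arm = trial$t_arm)  # blocked balance within strata
#' @export
simulate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_participants
  x <- generate_true_covariates(n, config$covariate_prevalence)
  mis <- apply_misclassification(x, config$error_rate, config$error_pattern,
                                 config$covariate_prevalence)
  t_arm <- stratified_block_randomise(mis$z_rand, config$block_size)
  disc <- apply_discovery(mis$is_error, t_arm, config$discovery_rate,
                          config$discovery_pattern, x, mis$z_rand)
  y <- generate_outcomes(x, t_arm, config)
  structure(
    data.frame(id = seq_len(n),
               x_true = x,
               z_rand = mis$z_rand,
               t_arm = t_arm,
               w_updated = disc$w_updated,
               y = y,
               is_error = mis$is_error,
               is_discovered = disc$is_discovered),
    class = c("trial_data", "data.frame"),
    block_size = config$block_size)
}

#' Export a simulated trial as a delimited table
#'
#' @param trial A `trial_data` data frame from [simulate_trial()].
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(trial, path) {
  stopifnot(inherits(trial, "trial_data"))
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  invisible(path)
}
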