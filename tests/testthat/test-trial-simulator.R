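test_that("true covariates are Bernoulli draws at the requested prevalence", {
  set.seed(101)
  expect_equal(generate_true_covariates(1000, 0), rep(0L, 1000))
  expect_equal(generate_true_covariates(1000, 1), rep(1L, 1000))
  x <- generate_true_covariates(1000, 0.5)
  expect_true(all(x %in% c(0L, 1L)))
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.25 / 1000))
  x75 <- generate_true_covariates(1e6, 0.75)
  expect_lt(abs(mean(x75) - 0.75), 3 * sqrt(0.75 * 0.25 / 1e6))
})

test_that("misclassification flips strata at the stratum-specific rates", {
  set.seed(102)
  x <- generate_true_covariates(2e5, 0.5)
  none <- apply_misclassification(x, 0, "equal")
  expect_identical(none$z_rand, x)
  expect_false(any(none$is_error))

  eq <- apply_misclassification(x, 0.2, "equal")
  expect_identical(eq$is_error, eq$z_rand != x)
  for (s in 0:1) {
    flip <- mean(eq$is_error[x == s])
    expect_lt(abs(flip - 0.2), 3 * sqrt(0.2 * 0.8 / sum(x == s)))
  }

  un <- apply_misclassification(x, 0.2, "unequal_3x", prevalence = 0.5)
  f0 <- mean(un$is_error[x == 0])
  f1 <- mean(un$is_error[x == 1])
  expect_lt(abs(f0 - 0.1), 3 * sqrt(0.1 * 0.9 / sum(x == 0)))
  expect_lt(abs(f1 - 0.3), 3 * sqrt(0.3 * 0.7 / sum(x == 1)))
})

test_that("permuted blocks balance arms within strata", {
  set.seed(103)
  # a stratum with 8 members and blocks of 4: every aligned block is 2/2
  z <- rep(0L, 8)
  t8 <- stratified_block_randomise(z, block_size = 4)
  expect_equal(sum(t8[1:4]), 2L)
  expect_equal(sum(t8[5:8]), 2L)

  # prefix imbalance never exceeds block_size / 2, any stratum sizes
  for (i in 1:25) {
    z <- generate_true_covariates(sample(50:400, 1), runif(1, 0.2, 0.8))
    t_arm <- stratified_block_randomise(z, block_size = 4)
    for (s in 0:1) {
      arm <- t_arm[z == s]
      if (length(arm) == 0L) next
      running <- cumsum(ifelse(arm == 1L, 1L, -1L))
      expect_lte(max(abs(running)), 2L)
    }
    # overall imbalance bounded by the sum of per-stratum bounds
    expect_lte(abs(sum(t_arm == 1L) - sum(t_arm == 0L)), 4L)
  }

  expect_error(stratified_block_randomise(rep(0L, 10), block_size = 3),
               "even")
})

test_that("a degenerate empty stratum is skipped", {
  set.seed(104)
  z <- rep(1L, 20)
  t_arm <- stratified_block_randomise(z, 4)
  expect_equal(abs(sum(t_arm) - 10L) <= 2L, TRUE)
})

test_that("block assignment within a block is a uniform permutation", {
  # each of the 6 possible 2/2 patterns in a block of 4 should be equally
  # likely; chi-square check over many blocks
  set.seed(105)
  n_blocks <- 3000
  z <- rep(0L, 4 * n_blocks)
  t_arm <- stratified_block_randomise(z, 4)
  pat <- apply(matrix(t_arm, nrow = 4), 2, paste, collapse = "")
  counts <- table(pat)
  expect_equal(length(counts), 6L)
  chisq <- sum((counts - n_blocks / 6)^2 / (n_blocks / 6))
  expect_lt(chisq, qchisq(0.999, df = 5))
})

test_that("discovery corrects discovered errors only, per arm rates", {
  set.seed(106)
  n <- 1e5
  x <- generate_true_covariates(n, 0.5)
  mis <- apply_misclassification(x, 0.2, "equal")
  t_arm <- stratified_block_randomise(mis$z_rand, 4)

  all_found <- apply_discovery(mis$is_error, t_arm, 0.5, "all",
                               x, mis$z_rand)
  expect_identical(all_found$w_updated, x)

  none_found <- apply_discovery(mis$is_error, t_arm, 0, "equal",
                                x, mis$z_rand)
  expect_identical(none_found$w_updated, mis$z_rand)

  unequal <- apply_discovery(mis$is_error, t_arm, 0.5,
                             "unequal_3x_intervention", x, mis$z_rand)
  expect_true(all(unequal$is_discovered <= mis$is_error))
  for (arm in 0:1) {
    sel <- mis$is_error & t_arm == arm
    d <- mean(unequal$is_discovered[sel])
    target <- c(0.25, 0.75)[arm + 1]
    expect_lt(abs(d - target),
              3 * sqrt(target * (1 - target) / sum(sel)))
  }
  # undiscovered errors keep the randomisation stratum, the rest the truth
  undisc <- mis$is_error & !unequal$is_discovered
  expect_identical(unequal$w_updated[undisc], mis$z_rand[undisc])
  expect_identical(unequal$w_updated[!undisc], x[!undisc])

  # no errors present: W == X == Z regardless of pattern
  clean <- apply_misclassification(x, 0, "equal")
  w0 <- apply_discovery(clean$is_error, t_arm, 0.5,
                        "unequal_3x_intervention", x, clean$z_rand)
  expect_identical(w0$w_updated, x)
  expect_false(any(w0$is_discovered))
})

test_that("outcomes follow the linear model cell means and unit variance", {
  set.seed(107)
  cfg <- scenario_config(alpha_coef = 0, beta_t = 0.2, beta_x = 1,
                         beta_tx = 0)
  n <- 4e5
  x <- generate_true_covariates(n, 0.5)
  t_arm <- rep(0:1, length.out = n)
  y <- generate_outcomes(x, t_arm, cfg)
  for (tt in 0:1) {
    for (xx in 0:1) {
      sel <- t_arm == tt & x == xx
      expect_lt(abs(mean(y[sel]) - cell_mean(cfg, tt, xx)),
                3 / sqrt(sum(sel)))
      expect_lt(abs(sd(y[sel]) - 1), 0.02)
    }
  }

  # interaction enters only the (T=1, X=1) cell
  cfg2 <- scenario_config(beta_t = 0, beta_x = 1, beta_tx = 0.4)
  y2 <- generate_outcomes(x, t_arm, cfg2)
  d1 <- mean(y2[t_arm == 1 & x == 1]) - mean(y2[t_arm == 0 & x == 1])
  d0 <- mean(y2[t_arm == 1 & x == 0]) - mean(y2[t_arm == 0 & x == 0])
  expect_lt(abs(d1 - 0.4), 3 * sqrt(2 / (n / 4)))
  expect_lt(abs(d0 - 0), 3 * sqrt(2 / (n / 4)))

  expect_error(generate_outcomes(x[1:10], t_arm, cfg), "length")
})

test_that("simulate_trial composes the processes and is reproducible", {
  cfg <- scenario_config(beta_t = 0.2, beta_x = 3, error_rate = 0.2,
                         discovery_rate = 0.5, discovery_pattern = "equal",
                         seed = 99)
  trial <- simulate_trial(cfg)
  expect_s3_class(trial, "trial_data")
  expect_equal(nrow(trial), 1000L)
  expect_identical(trial$is_error, trial$z_rand != trial$x_true)
  expect_true(all(trial$is_discovered <= trial$is_error))
  undisc <- trial$is_error & !trial$is_discovered
  expect_identical(trial$w_updated[undisc], trial$z_rand[undisc])
  expect_identical(trial$w_updated[!undisc], trial$x_true[!undisc])
  expect_lte(max_prefix_imbalance(trial), 2L)

  # identical config + seed => identical trial
  expect_identical(simulate_trial(cfg), trial)

  # no errors => Z == X == W
  clean <- simulate_trial(scenario_config(error_rate = 0, seed = 1))
  expect_identical(clean$z_rand, clean$x_true)
  expect_identical(clean$w_updated, clean$x_true)

  # full discovery => W == X
  full <- simulate_trial(scenario_config(error_rate = 0.3,
                                         discovery_pattern = "all",
                                         seed = 2))
  expect_identical(full$w_updated, full$x_true)
})

test_that("misclassification is independent of treatment assignment", {
  set.seed(108)
  cfg <- scenario_config(error_rate = 0.2, discovery_rate = 0.5,
                         discovery_pattern = "equal")
  err_by_arm <- matrix(0, 60, 2)
  for (j in 1:60) {
    trial <- simulate_trial(cfg, seed = NULL)
    err_by_arm[j, ] <- c(mean(trial$is_error[trial$t_arm == 0]),
                         mean(trial$is_error[trial$t_arm == 1]))
  }
  diff <- mean(err_by_arm[, 2] - err_by_arm[, 1])
  se <- sd(err_by_arm[, 2] - err_by_arm[, 1]) / sqrt(60)
  expect_lt(abs(diff), 4 * se)
})

test_that("trial data export writes a readable delimited table", {
  trial <- simulate_trial(scenario_config(error_rate = 0.1, seed = 5,
                                          n_participants = 40))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_data(trial, path)
  back <- utils::read.csv(path)
  expect_equal(names(back),
               c("id", "x_true", "z_rand", "t_arm", "w_updated", "y",
                 "is_error", "is_discovered"))
  expect_equal(back$y, trial$y)
})
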