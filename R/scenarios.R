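#' Names of the study sections
#'
#' The simulation study is organised into eight sections, each a grid of
#' scenarios sharing a question: the effect of stratification errors on the
#' correlation between arm means; treatment-effect estimation when all, or
#' only some, errors are discovered (plus a no-error reference grid);
#' interaction estimation under full or partial discovery; and sensitivity
#' grids varying the sample size and covariate prevalence.
#'
#' @return Character vector of section names.
#' @export
study_sections <- function() {
  c("correlation", "full_discovery_TE", "no_error_reference",
    "partial_discovery_TE", "interaction_full", "interaction_partial",
    "sensitivity_TE", "sensitivity_interaction")
}

#' Build the scenario grid for one study section
#'
#' Enumerates the full cross-product of simulation factors for a section,
#' in a fixed deterministic order, together with the analysis methods the
#' section compares. The section sizes are 18, 16, 4, 32, 12, 24, 8 and 8
#' scenarios (122 in total).
#'
#' @param section One of [study_sections()].
#' @return An object of class `study_section`: a list with elements `name`,
#'   `scenarios` (list of [scenario_config()]), `adjustments` (covariate
#'   adjustments for the main-effects treatment model) and
#'   `interaction_covariates` (stratum variables for the interaction model;
#'   empty when the section does not study interactions).
#' @examples
#' grid <- scenario_grid("full_discovery_TE")
#' length(grid$scenarios)  # 16
#' @export
scenario_grid <- function(section = study_sections()) {
  section <- match.arg(section)
  adjustments <- character(0)
  interaction_covariates <- character(0)

  configs <- switch(section,
    correlation = {
      cells <- expand.grid(beta_x = c(1, 3),
                           error_rate = seq(0, 0.4, by = 0.05),
                           KEEP.OUT.ATTRS = FALSE)
      lapply(seq_len(nrow(cells)), function(i) {
        scenario_config(beta_t = 0, beta_x = cells$beta_x[i],
                        error_rate = cells$error_rate[i],
                        error_pattern = "equal",
                        discovery_pattern = "all")
      })
    },
    full_discovery_TE = {
      adjustments <- c("none", "randomisation_Z", "true_X")
      cells <- expand.grid(beta_t = c(0, 0.2), beta_x = c(1, 3),
                           error_rate = c(0.01, 0.2),
                           error_pattern = c("equal", "unequal_3x"),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
      lapply(seq_len(nrow(cells)), function(i) {
        scenario_config(beta_t = cells$beta_t[i], beta_x = cells$beta_x[i],
                        error_rate = cells$error_rate[i],
                        error_pattern = cells$error_pattern[i],
                        discovery_pattern = "all")
      })
    },
    no_error_reference = {
      adjustments <- c("none", "randomisation_Z", "true_X")
      cells <- expand.grid(beta_t = c(0, 0.2), beta_x = c(1, 3),
                           KEEP.OUT.ATTRS = FALSE)
      lapply(seq_len(nrow(cells)), function(i) {
        scenario_config(beta_t = cells$beta_t[i], beta_x = cells$beta_x[i],
                        error_rate = 0, discovery_pattern = "all")
      })
    },
    partial_discovery_TE = {
      adjustments <- c("none", "randomisation_Z", "true_X", "updated_W")
      cells <- expand.grid(beta_t = c(0, 0.2), beta_x = c(1, 3),
                           error_rate = c(0.01, 0.2),
                           error_pattern = c("equal", "unequal_3x"),
                           discovery_pattern = c("equal",
                                                 "unequal_3x_intervention"),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
      lapply(seq_len(nrow(cells)), function(i) {
        scenario_config(beta_t = cells$beta_t[i], beta_x = cells$beta_x[i],
                        error_rate = cells$error_rate[i],
                        error_pattern = cells$error_pattern[i],
                        discovery_rate = 0.5,
                        discovery_pattern = cells$discovery_pattern[i])
      })
    },
    interaction_full = {
      adjustments <- c("none", "randomisation_Z", "true_X")
      interaction_covariates <- c("randomisation_Z", "true_X")
      effects <- data.frame(beta_t = c(0.2, 0.1, 0), beta_tx = c(0, 0.2, 0.4))
      cells <- expand.grid(effect = seq_len(nrow(effects)),
                           error_rate = c(0.01, 0.2),
                           error_pattern = c("equal", "unequal_3x"),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
      lapply(seq_len(nrow(cells)), function(i) {
        e <- cells$effect[i]
        scenario_config(beta_t = effects$beta_t[e], beta_x = 1,
                        beta_tx = effects$beta_tx[e],
                        error_rate = cells$error_rate[i],
                        error_pattern = cells$error_pattern[i],
                        discovery_pattern = "all")
      })
    },
    interaction_partial = {
      adjustments <- c("none", "randomisation_Z", "true_X", "updated_W")
      interaction_covariates <- c("randomisation_Z", "true_X", "updated_W")
      effects <- data.frame(beta_t = c(0.2, 0.1, 0), beta_tx = c(0, 0.2, 0.4))
      cells <- expand.grid(effect = seq_len(nrow(effects)),
                           error_rate = c(0.01, 0.2),
                           error_pattern = c("equal", "unequal_3x"),
                           discovery_pattern = c("equal",
                                                 "unequal_3x_intervention"),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
      lapply(seq_len(nrow(cells)), function(i) {
        e <- cells$effect[i]
        scenario_config(beta_t = effects$beta_t[e], beta_x = 1,
                        beta_tx = effects$beta_tx[e],
                        error_rate = cells$error_rate[i],
                        error_pattern = cells$error_pattern[i],
                        discovery_rate = 0.5,
                        discovery_pattern = cells$discovery_pattern[i])
      })
    },
    sensitivity_TE = {
      adjustments <- c("none", "randomisation_Z", "true_X", "updated_W")
      designs <- data.frame(n = c(200L, 1000L), prevalence = c(0.5, 0.75))
      cells <- expand.grid(design = 1:2,
                           error_pattern = c("equal", "unequal_3x"),
                           discovery_pattern = c("equal",
                                                 "unequal_3x_intervention"),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
      lapply(seq_len(nrow(cells)), function(i) {
        d <- cells$design[i]
        scenario_config(n_participants = designs$n[d],
                        covariate_prevalence = designs$prevalence[d],
                        beta_t = 0, beta_x = 3,
                        error_rate = 0.2,
                        error_pattern = cells$error_pattern[i],
                        discovery_rate = 0.5,
                        discovery_pattern = cells$discovery_pattern[i])
      })
    },
    sensitivity_interaction = {
      adjustments <- c("none", "randomisation_Z", "true_X", "updated_W")
      interaction_covariates <- c("randomisation_Z", "true_X", "updated_W")
      designs <- data.frame(n = c(200L, 1000L), prevalence = c(0.5, 0.75))
      cells <- expand.grid(design = 1:2,
                           error_pattern = c("equal", "unequal_3x"),
                           discovery_pattern = c("equal",
                                                 "unequal_3x_intervention"),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
      lapply(seq_len(nrow(cells)), function(i) {
        d <- cells$design[i]
        scenario_config(n_participants = designs$n[d],
                        covariate_prevalence = designs$prevalence[d],
                        beta_t = 0, beta_x = 1, beta_tx = 0.4,
                        error_rate = 0.2,
                        error_pattern = cells$error_pattern[i],
                        discovery_rate = 0.5,
                        discovery_pattern = cells$discovery_pattern[i])
      })
    })

  for (i in seq_along(configs)) {
    configs[[i]]$scenario_id <- paste0(section, "_", configs[[i]]$scenario_id)
  }
  ids <- vapply(configs, `[[`, character(1), "scenario_id")
  stopifnot(!anyDuplicated(ids))
  structure(list(name = section,
                 scenarios = configs,
                 adjustments = adjustments,
                 interaction_covariates = interaction_covariates),
            class = "study_section")
}

#' @export
print.study_section <- function(x, ...) {
  cat(sprintf("<study_section> %s: %d scenarios\n", x$name,
              length(x$scenarios)))
  if (length(x$adjustments)) {
    cat("  main-effects adjustments:", paste(x$adjustments, collapse = ", "),
        "\n")
  }
  if (length(x$interaction_covariates)) {
    cat("  interaction covariates:",
        paste(x$interaction_covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Deterministic per-repetition seed
#'
#' Derives a 32-bit seed for one repetition of one scenario from a master
#' seed. Repetitions and scenarios get distinct substreams, so a study can
#' be split across workers by scenario (or by repetition chunk) and still
#' reproduce exactly.
#'
#' @param seed Master integer seed.
#' @param rep Repetition number (1-based).
#' @param scenario_index Global scenario index (0-based offset).
#' @return An integer seed below 2^31.
#' @export
rep_seed <- function(seed, rep, scenario_index = 0L) {
  as.integer((as.numeric(seed) %% 2147483647 + 1000003 * scenario_index +
                7919 * rep) %% 2147483647)
}

#' Run one scenario: simulate, analyse, summarise
#'
#' Generates `n_reps` independent trials from `config`, analyses each with
#' the requested main-effects and interaction models (all methods analyse
#' the same simulated dataset within a repetition), and summarises every
#' (model, adjustment, parameter) cell with [summarise_performance()]. Arm
#' sample means are recorded per repetition and their correlation across
#' repetitions is reported via [arm_mean_correlation()].
#'
#' True values used for bias and coverage: the treatment coefficient of the
#' main-effects model targets the marginal effect
#' \eqn{\beta_T + \pi \beta_{TX}}; in the interaction model the treatment
#' coefficient targets \eqn{\beta_T} (the stratum-0 subgroup effect) and the
#' interaction coefficient targets \eqn{\beta_{TX}}.
#'
#' @param config A [scenario_config()].
#' @param adjustments Character vector of adjustments for the main-effects
#'   model (subset of `"none"`, `"randomisation_Z"`, `"true_X"`,
#'   `"updated_W"`); may be empty.
#' @param interaction_covariates Character vector of stratum variables for
#'   the interaction model; may be empty.
#' @param n_reps Number of repetitions (defaults to `config$n_reps`).
#' @param seed Master seed for this scenario (defaults to `config$seed`; if
#'   `NULL` the current RNG state is used and the run is not reproducible).
#' @param scenario_index Offset passed to [rep_seed()] so different
#'   scenarios of a study use disjoint substreams.
#' @return An object of class `scenario_result`: a list with `scenario_id`,
#'   `config`, `performance` (data frame), `arm_means` (data frame with
#'   columns `rep`, `mean_control`, `mean_intervention`), `correlation`
#'   (from [arm_mean_correlation()]) and `n_failed` (repetitions dropped
#'   because a model could not be fitted).
#' @examples
#' res <- run_scenario(scenario_config(beta_t = 0.2, beta_x = 1, seed = 7),
#'                     adjustments = c("none", "true_X"), n_reps = 50)
#' res$performance[, c("adjustment", "bias", "rejection_pct")]
#' @export
run_scenario <- function(config,
                         adjustments = character(0),
                         interaction_covariates = character(0),
                         n_reps = config$n_reps,
                         seed = config$seed,
                         scenario_index = 0L) {
  stopifnot(inherits(config, "scenario_config"))
  check_count(n_reps, "n_reps")

  cells <- list()
  for (adj in adjustments) {
    cells[[paste0("main.", adj, ".treatment")]] <-
      list(model = "main_effects", adjustment = adj, parameter = "treatment",
           true_value = true_marginal_effect(config))
  }
  for (cv in interaction_covariates) {
    cells[[paste0("int.", cv, ".treatment")]] <-
      list(model = "interaction", adjustment = cv, parameter = "treatment",
           true_value = config$beta_t)
    cells[[paste0("int.", cv, ".interaction")]] <-
      list(model = "interaction", adjustment = cv, parameter = "interaction",
           true_value = config$beta_tx)
  }
  n_cells <- length(cells)

  est <- matrix(NA_real_, n_reps, n_cells)
  varhat <- matrix(NA_real_, n_reps, n_cells)
  rej <- matrix(NA, n_reps, n_cells)
  cov <- matrix(NA, n_reps, n_cells)
  mean_c <- numeric(n_reps)
  mean_i <- numeric(n_reps)
  failed <- logical(n_reps)

  for (j in seq_len(n_reps)) {
    if (!is.null(seed)) set.seed(rep_seed(seed, j, scenario_index))
    trial <- simulate_trial(config, seed = NULL)
    mean_c[j] <- mean(trial$y[trial$t_arm == 0L])
    mean_i[j] <- mean(trial$y[trial$t_arm == 1L])
    k <- 0L
    ok <- TRUE
    res_j <- vector("list", n_cells)
    for (adj in adjustments) {
      k <- k + 1L
      fr <- tryCatch(analyse_treatment_effect(trial, adj),
                     error = function(e) NULL)
      if (is.null(fr)) { ok <- FALSE; break }
      res_j[[k]] <- fr
    }
    if (ok) {
      for (cv in interaction_covariates) {
        fr <- tryCatch(analyse_interaction(trial, cv),
                       error = function(e) NULL)
        if (is.null(fr)) { ok <- FALSE; break }
        res_j[[k + 1L]] <- fr[1L, ]
        res_j[[k + 2L]] <- fr[2L, ]
        k <- k + 2L
      }
    }
    if (!ok) { failed[j] <- TRUE; next }
    for (k in seq_len(n_cells)) {
      fr <- res_j[[k]]
      tv <- cells[[k]]$true_value
      est[j, k] <- fr$estimate
      varhat[j, k] <- fr$model_se^2
      rej[j, k] <- fr$reject_5pct
      cov[j, k] <- fr$ci_low <= tv && tv <= fr$ci_high
    }
  }

  keep <- !failed
  n_failed <- sum(failed)
  if (n_failed > 0L) {
    message(sprintf("scenario %s: dropped %d of %d repetitions (model fits failed)",
                    config$scenario_id, n_failed, n_reps))
  }

  perf <- NULL
  if (n_cells > 0L && sum(keep) >= 2L) {
    perf <- do.call(rbind, lapply(seq_len(n_cells), function(k) {
      cl <- cells[[k]]
      cbind(data.frame(scenario_id = config$scenario_id,
                       model = cl$model, adjustment = cl$adjustment,
                       parameter = cl$parameter, true_value = cl$true_value),
            summarise_performance(est[keep, k], varhat[keep, k],
                                  rej[keep, k], cov[keep, k],
                                  cl$true_value))
    }))
  }

  arm_means <- data.frame(rep = which(keep),
                          mean_control = mean_c[keep],
                          mean_intervention = mean_i[keep])
  correlation <- if (sum(keep) >= 4L) {
    arm_mean_correlation(arm_means$mean_control, arm_means$mean_intervention)
  } else NULL

  structure(list(scenario_id = config$scenario_id,
                 config = config,
                 performance = perf,
                 arm_means = arm_means,
                 correlation = correlation,
                 n_failed = n_failed),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (%d repetitions", x$scenario_id,
              nrow(x$arm_means)))
  if (x$n_failed > 0L) cat(sprintf(", %d failed", x$n_failed))
  cat(")\n")
  if (!is.null(x$performance)) {
    print(x$performance[, c("model", "adjustment", "parameter", "bias",
                            "emp_se", "mod_se", "coverage_pct",
                            "rejection_pct")], digits = 3)
  }
  if (!is.null(x$correlation)) {
    cat(sprintf("arm-mean correlation: %.3f (Fisher-z MCSE %.4f)\n",
                x$correlation$correlation, x$correlation$fisher_z_mcse))
  }
  invisible(x)
}

config_columns <- function(config) {
  data.frame(n_participants = config$n_participants,
             covariate_prevalence = config$covariate_prevalence,
             beta_t = config$beta_t, beta_x = config$beta_x,
             beta_tx = config$beta_tx,
             error_rate = config$error_rate,
             error_pattern = config$error_pattern,
             discovery_rate = config$discovery_rate,
             discovery_pattern = config$discovery_pattern)
}

#' Run study sections and write result tables
#'
#' Runs every scenario of the requested sections with [run_scenario()],
#' writing one performance CSV per section (plus an arm-mean-correlation CSV
#' for the correlation section) and a JSON manifest recording the seed,
#' repetition count and any skipped or failed scenarios. Results are
#' reproducible for a fixed `(sections, n_reps, seed)` regardless of
#' `workers`, because each scenario derives its own substream via
#' [rep_seed()].
#'
#' @param sections Character vector of section names (see
#'   [study_sections()]).
#' @param n_reps Repetitions per scenario (`NULL` uses each scenario's
#'   default, 10000).
#' @param seed Master integer seed.
#' @param out_dir Output directory, created if needed; `NULL` suppresses
#'   file output.
#' @param workers Number of parallel workers (forked; scenario-level).
#' @return Invisibly, a named list (one element per section) of lists of
#'   `scenario_result` objects.
#' @export
run_study <- function(sections = study_sections(), n_reps = NULL, seed = 1L,
                      out_dir = NULL, workers = 1L) {
  sections <- match.arg(sections, study_sections(), several.ok = TRUE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  all_sections <- study_sections()
  skipped <- character(0)
  results <- list()

  for (section in sections) {
    grid <- scenario_grid(section)
    offset <- (match(section, all_sections) - 1L) * 1000L
    run_one <- function(i) {
      cfg <- grid$scenarios[[i]]
      tryCatch(
        run_scenario(cfg,
                     adjustments = grid$adjustments,
                     interaction_covariates = grid$interaction_covariates,
                     n_reps = if (is.null(n_reps)) cfg$n_reps else n_reps,
                     seed = seed, scenario_index = offset + i),
        error = function(e) {
          message(sprintf("skipping scenario %s: %s", cfg$scenario_id,
                          conditionMessage(e)))
          NULL
        })
    }
    idx <- seq_along(grid$scenarios)
    res <- if (workers > 1L) {
      parallel::mclapply(idx, run_one, mc.cores = workers)
    } else {
      lapply(idx, run_one)
    }
    names(res) <- vapply(grid$scenarios, `[[`, character(1), "scenario_id")
    skipped <- c(skipped, names(res)[vapply(res, is.null, logical(1))])
    res <- Filter(Negate(is.null), res)
    results[[section]] <- res

    if (!is.null(out_dir) && length(res) > 0L) {
      perf <- do.call(rbind, lapply(res, function(r) {
        if (is.null(r$performance)) return(NULL)
        cbind(r$performance[, "scenario_id", drop = FALSE],
              config_columns(r$config),
              r$performance[, setdiff(names(r$performance), "scenario_id")])
      }))
      if (!is.null(perf)) {
        utils::write.csv(perf,
                         file.path(out_dir,
                                   paste0(section, "_performance.csv")),
                         row.names = FALSE)
      }
      if (section == "correlation") {
        corr <- do.call(rbind, lapply(res, function(r) {
          cbind(data.frame(scenario_id = r$scenario_id),
                config_columns(r$config),
                data.frame(correlation = r$correlation$correlation,
                           fisher_z_mcse = r$correlation$fisher_z_mcse,
                           n_reps = r$correlation$n_reps))
        }))
        utils::write.csv(corr,
                         file.path(out_dir, "correlation_arm_means.csv"),
                         row.names = FALSE)
      }
    }
  }

  if (!is.null(out_dir)) {
    manifest <- list(package = "mistrat",
                     version = as.character(utils::packageVersion("mistrat")),
                     r_version = R.version.string,
                     sections = sections,
                     n_reps = if (is.null(n_reps)) "scenario default" else
                       n_reps,
                     seed = seed,
                     skipped_scenarios = skipped,
                     timestamp = format(Sys.time(), tz = "UTC",
                                        usetz = TRUE))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}
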