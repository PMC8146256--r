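#' Build an evaluation configuration
#'
#' Assembles the full evaluation design: the synthetic cohort, the sample
#' groups (stratified subsample fractions with their draw counts), the
#' matching methods to compare, propensity-model settings, time-at-risk
#' settings and calibration settings. The default grid mirrors a
#' full-population analysis plus 10%/1%/0.5% subsample groups with
#' 1/5/50/100 draws and seven analysis cells per group (pre-match, PSM at
#' calipers 0.10/0.20, CM at fine balance and maximum SMD
#' 0.01/0.05/0.10); override `sample_groups`/`methods` for smaller
#' designs.
#'
#' @param n_subjects Cohort size for the simulation.
#' @param master_seed Single seed from which every random stream (cohort,
#'   draws, folds, matching order, MCMC) is derived.
#' @param sample_groups List of lists with `name`, `fraction`, `n_draws`.
#' @param methods List of lists with `name` and either
#'   `type = "psm", caliper_fraction = ...` or
#'   `type = "cm", balance_criterion = ...`.
#' @param min_frequency Candidate-covariate frequency threshold for the
#'   propensity model (default 0.001).
#' @param cm_min_frequency Optional stricter threshold used only to define
#'   the CM matching covariates (the full-population memory-driven
#'   asymmetry); `NULL` (default) shares the propensity model's set.
#' @param cv_folds Cross-validation folds for the LASSO.
#' @param persistence_gap_days,min_days Time-at-risk settings.
#' @param mcmc_iterations,mcmc_burn_in ESE credible-interval settings.
#' @param balance_threshold Absolute SMD below which a covariate is
#'   balanced.
#' @param simulation Extra arguments passed to [sim_config()].
#' @return A list of class `evaluation_config`, writable as YAML.
#' @export
evaluation_config <- function(n_subjects = 20000L,
                              master_seed = 1L,
                              sample_groups = NULL,
                              methods = NULL,
                              min_frequency = 0.001,
                              cm_min_frequency = NULL,
                              cv_folds = 10L,
                              persistence_gap_days = 30L,
                              min_days = 1L,
                              mcmc_iterations = 4000L,
                              mcmc_burn_in = 1000L,
                              balance_threshold = 0.10,
                              simulation = list()) {
  sample_groups <- sample_groups %||% list(
    list(name = "full", fraction = 1.0, n_draws = 1L),
    list(name = "10pct", fraction = 0.10, n_draws = 5L),
    list(name = "1pct", fraction = 0.01, n_draws = 50L),
    list(name = "0.5pct", fraction = 0.005, n_draws = 100L)
  )
  methods <- methods %||% list(
    list(name = "psm-0.10", type = "psm", caliper_fraction = 0.10),
    list(name = "psm-0.20", type = "psm", caliper_fraction = 0.20),
    list(name = "cm-fine", type = "cm", balance_criterion = 0),
    list(name = "cm-0.01", type = "cm", balance_criterion = 0.01),
    list(name = "cm-0.05", type = "cm", balance_criterion = 0.05),
    list(name = "cm-0.10", type = "cm", balance_criterion = 0.10)
  )
  structure(
    list(n_subjects = as.integer(n_subjects),
         master_seed = as.integer(master_seed),
         sample_groups = sample_groups, methods = methods,
         min_frequency = min_frequency,
         cm_min_frequency = cm_min_frequency,
         cv_folds = as.integer(cv_folds),
         persistence_gap_days = as.integer(persistence_gap_days),
         min_days = as.integer(min_days),
         mcmc_iterations = as.integer(mcmc_iterations),
         mcmc_burn_in = as.integer(mcmc_burn_in),
         balance_threshold = balance_threshold,
         simulation = simulation),
    class = "evaluation_config"
  )
}

read_evaluation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(evaluation_config, cfg)
}

#' Run the full matching evaluation
#'
#' Generates the synthetic cohort, then for every sample group draws the
#' stratified subsamples and, within each draw, refits the propensity
#' model, extracts the matching covariates, applies every configured
#' matcher, and records matched pairs and balance. Negative-control
#' hazard ratios are estimated from post-match observations pooled across
#' all draws of a group, the expected systematic error is computed per
#' analysis cell with MCMC credible intervals, and the safety outcome is
#' estimated and calibrated per cell. All outputs are plain CSV/JSON under
#' `out_dir`; the run is deterministic given `master_seed`.
#'
#' @param config An [evaluation_config()], a YAML path, or a list of
#'   arguments for [evaluation_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, the result bundle (also written to disk):
#'   `cells`, `balance`, `estimates`, `ese`, `safety`.
#' @export
run_evaluation <- function(config, out_dir) {
  if (is.character(config)) config <- read_evaluation_config(config)
  if (!inherits(config, "evaluation_config")) {
    config <- do.call(evaluation_config, config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "matched_pairs"), showWarnings = FALSE)
  seed <- config$master_seed

  sim_args <- utils::modifyList(
    list(n_subjects = config$n_subjects,
         seed = derive_seed(seed, "cohort")),
    config$simulation
  )
  cohort <- generate_cohort(do.call(sim_config, sim_args))
  nc_ids <- cohort$outcome_info$outcome_id[cohort$outcome_info$negative_control]

  cells <- list(); balance_rows <- list(); est_rows <- list()
  ese_rows <- list(); safety_rows <- list()

  for (g in config$sample_groups) {
    draws <- if (g$fraction >= 1) list(cohort) else {
      draw_subsamples(cohort, g$fraction, g$n_draws,
                      seed = derive_seed(seed, paste0("draws_", g$name)))
    }
    n_draws <- length(draws)
    per_method_ids <- stats::setNames(
      replicate(length(config$methods), vector("list", n_draws),
                simplify = FALSE),
      vapply(config$methods, `[[`, character(1), "name"))
    pre_reports_m <- list(); pre_reports_c <- list()
    post_reports <- list(); pair_counts <- list(); feasible <- list()
    tars <- vector("list", n_draws)
    n_matching_covs <- numeric(n_draws)

    for (d in seq_len(n_draws)) {
      dc <- draws[[d]]
      cand <- select_candidate_covariates(dc, config$min_frequency)
      ps <- fit_propensity_model(
        dc, cand, cv_folds = config$cv_folds,
        seed = derive_seed(seed, paste0("ps_", g$name), d))
      scores <- predict_scores(ps, dc)
      mcov <- extract_matching_covariates(ps)
      cm_mcov <- mcov
      if (!is.null(config$cm_min_frequency) &&
          config$cm_min_frequency > config$min_frequency) {
        cm_cand <- select_candidate_covariates(dc, config$cm_min_frequency)
        cm_ps <- fit_propensity_model(
          dc, cm_cand, cv_folds = config$cv_folds,
          seed = derive_seed(seed, paste0("cmps_", g$name), d))
        cm_mcov <- extract_matching_covariates(cm_ps)
      }
      n_matching_covs[d] <- length(mcov)
      pre_reports_m[[d]] <- balance_table(dc, NULL, mcov, draw_id = d)
      pre_reports_c[[d]] <- balance_table(dc, NULL, cand, draw_id = d)
      tars[[d]] <- build_time_at_risk(
        dc, persistence_gap_days = config$persistence_gap_days,
        min_days = config$min_days)

      for (m in config$methods) {
        res <- tryCatch({
          if (m$type == "psm") {
            greedy_match(scores, cohort_arms(dc),
                         caliper_fraction = m$caliper_fraction,
                         seed = derive_seed(seed, paste0("psm_", g$name), d))
          } else {
            cardinality_match(
              dc, cm_mcov,
              cm_config(m$balance_criterion,
                        seed = derive_seed(seed, paste0("cm_", g$name), d)),
              scores = scores)
          }
        }, error = function(e) {
          warning(sprintf("cell %s/%s draw %d failed: %s", g$name, m$name,
                          d, conditionMessage(e)))
          NULL
        })
        if (is.null(res)) next
        mc_scope <- if (m$type == "cm") cm_mcov else mcov
        key <- m$name
        per_method_ids[[key]][[d]] <- matched_ids(res)
        pair_counts[[key]] <- c(pair_counts[[key]], nrow(res$pairs))
        feasible[[key]] <- c(feasible[[key]], res$feasible)
        if (res$feasible && nrow(res$pairs)) {
          post_reports[[key]]$matching[[d]] <-
            balance_table(dc, res, mc_scope, draw_id = d)
          post_reports[[key]]$candidate[[d]] <-
            balance_table(dc, res, cand, draw_id = d)
        }
        write_match_result(
          res, file.path(out_dir, "matched_pairs",
                         sprintf("%s_%s_draw%03d.csv", g$name, key, d)))
      }
    }

    # pre-match cell
    cells[[length(cells) + 1]] <- data.frame(
      sample_group = g$name, method = "pre-match", n_draws = n_draws,
      avg_matched_pairs = NA_real_, n_feasible = NA_integer_,
      avg_matching_covariates = mean(n_matching_covs))
    balance_rows[[length(balance_rows) + 1]] <-
      tag_balance(pool_reports(pre_reports_m)$pooled, g$name, "pre-match",
                  "matching")
    balance_rows[[length(balance_rows) + 1]] <-
      tag_balance(pool_reports(pre_reports_c)$pooled, g$name, "pre-match",
                  "candidate")
    cell_outcomes <- function(tar_stack, method_name) {
      est <- fit_outcome_models(tar_stack, cohort$outcomes, nc_ids)
      est_rows[[length(est_rows) + 1]] <<- cbind(
        sample_group = g$name, method = method_name, est)
      usable <- sum(est$estimable)
      if (usable >= 2) {
        ese <- ese_credible_interval(
          est, iterations = config$mcmc_iterations,
          burn_in = config$mcmc_burn_in,
          seed = derive_seed(seed, paste0("mcmc_", g$name, method_name)))
        ese_rows[[length(ese_rows) + 1]] <<- data.frame(
          sample_group = g$name, method = method_name,
          ese = ese$point, ci_low = ese$ci_low, ci_high = ese$ci_high,
          mu = ese$model$mu, sigma = ese$model$sigma,
          n_controls_used = ese$model$n_used)
        sf <- fit_cox(tar_stack, cohort$outcomes, "safety")
        if (sf$estimable) {
          cal <- calibrate_estimate(ese$model, sf$log_hr, sf$se)
          safety_rows[[length(safety_rows) + 1]] <<- data.frame(
            sample_group = g$name, method = method_name,
            hr = exp(sf$log_hr),
            ci_low = exp(cal$uncalibrated$ci_low),
            ci_high = exp(cal$uncalibrated$ci_high),
            p = cal$uncalibrated$p,
            cal_hr = exp(cal$log_hr), cal_ci_low = exp(cal$ci_low),
            cal_ci_high = exp(cal$ci_high), cal_p = cal$p,
            n_events = sf$n_events)
        }
      }
    }
    cell_outcomes(do.call(rbind, tars), "pre-match")

    for (m in config$methods) {
      key <- m$name
      cells[[length(cells) + 1]] <- data.frame(
        sample_group = g$name, method = key, n_draws = n_draws,
        avg_matched_pairs = mean(pair_counts[[key]] %||% NA_real_),
        n_feasible = sum(feasible[[key]] %||% logical(0)),
        avg_matching_covariates = mean(n_matching_covs))
      for (scope in c("matching", "candidate")) {
        reps <- Filter(Negate(is.null), post_reports[[key]][[scope]])
        if (length(reps)) {
          balance_rows[[length(balance_rows) + 1]] <-
            tag_balance(pool_reports(reps)$pooled, g$name, key, scope)
        }
      }
      tar_stack <- do.call(rbind, lapply(seq_len(n_draws), function(d) {
        ids <- per_method_ids[[key]][[d]]
        if (is.null(ids) || !length(ids)) return(NULL)
        t <- tars[[d]]
        t[t$subject_id %in% ids, , drop = FALSE]
      }))
      if (!is.null(tar_stack) && nrow(tar_stack)) {
        cell_outcomes(tar_stack, key)
      }
    }
  }

  bundle <- list(
    cells = do.call(rbind, cells),
    balance = do.call(rbind, balance_rows),
    estimates = do.call(rbind, est_rows),
    ese = if (length(ese_rows)) do.call(rbind, ese_rows) else NULL,
    safety = if (length(safety_rows)) do.call(rbind, safety_rows) else NULL
  )
  utils::write.csv(bundle$cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$balance, file.path(out_dir, "balance.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$estimates, file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$ese)) {
    utils::write.csv(bundle$ese, file.path(out_dir, "ese.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$safety)) {
    utils::write.csv(bundle$safety, file.path(out_dir, "safety.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(master_seed = seed, n_subjects = config$n_subjects,
         balance_threshold = config$balance_threshold),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}

tag_balance <- function(pooled, group, method, scope) {
  cbind(sample_group = group, method = method, scope = scope,
        pooled[, c("covariate_id", "draw_id", "smd", "defined")])
}

#' Summarize an evaluation result bundle
#'
#' Reads the CSV bundle written by [run_evaluation()] and prints per-cell
#' retention, imbalance counts/proportions, expected systematic error and
#' (where estimable) calibrated safety-outcome hazard ratios.
#'
#' @param results_dir Directory written by [run_evaluation()].
#' @param threshold Balance threshold; default read from the run metadata.
#' @return Invisibly, a list of summary data frames.
#' @export
summarize_evaluation <- function(results_dir, threshold = NULL) {
  if (!dir.exists(results_dir) ||
      !file.exists(file.path(results_dir, "cells.csv"))) {
    stop_no_call("no evaluation bundle found in ", results_dir)
  }
  run <- jsonlite::read_json(file.path(results_dir, "run.json"),
                             simplifyVector = TRUE)
  threshold <- threshold %||% run$balance_threshold %||% 0.10
  cells <- utils::read.csv(file.path(results_dir, "cells.csv"))
  balance <- utils::read.csv(file.path(results_dir, "balance.csv"))
  bal_sum <- do.call(rbind, lapply(
    split(balance, balance[c("sample_group", "method", "scope")],
          drop = TRUE),
    function(b) {
      smd <- b$smd[!is.na(b$smd)]
      data.frame(sample_group = b$sample_group[1], method = b$method[1],
                 scope = b$scope[1], n_smd = length(smd),
                 mean_abs_smd = mean(abs(smd)),
                 max_abs_smd = if (length(smd)) max(abs(smd)) else NA_real_,
                 imbalanced = sum(abs(smd) >= threshold),
                 imbalanced_prop = mean(abs(smd) >= threshold))
    }))
  rownames(bal_sum) <- NULL
  out <- list(cells = cells, balance_summary = bal_sum)
  cat("== Post-match sample size (average pairs per draw) ==\n")
  print(cells, row.names = FALSE)
  cat("\n== Covariate balance (pooled across draws; |SMD| >= ",
      threshold, " imbalanced) ==\n", sep = "")
  print(bal_sum, row.names = FALSE, digits = 3)
  ese_path <- file.path(results_dir, "ese.csv")
  if (file.exists(ese_path)) {
    out$ese <- utils::read.csv(ese_path)
    cat("\n== Expected systematic error ==\n")
    print(out$ese, row.names = FALSE, digits = 3)
  }
  safety_path <- file.path(results_dir, "safety.csv")
  if (file.exists(safety_path)) {
    out$safety <- utils::read.csv(safety_path)
    cat("\n== Safety outcome (uncalibrated and calibrated HR) ==\n")
    print(out$safety, row.names = FALSE, digits = 3)
  }
  invisible(out)
}

#' Violin-style summary figure of pooled SMD distributions
#'
#' @param balance Long balance table from the bundle (`balance.csv`).
#' @param scope `"matching"` or `"candidate"`.
#' @return A ggplot object.
#' @export
plot_smd_distributions <- function(balance, scope = "matching") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_no_call("ggplot2 is required for plotting")
  }
  b <- balance[balance$scope == scope & !is.na(balance$smd), ]
  method <- smd <- NULL # quiet R CMD check; evaluated inside aes()
  ggplot2::ggplot(b, ggplot2::aes(x = method, y = smd)) +
    ggplot2::geom_violin(fill = "grey85", scale = "width") +
    ggplot2::geom_hline(yintercept = c(-0.1, 0.1), linetype = 2,
                        colour = "red3") +
    ggplot2::facet_wrap(~sample_group) +
    ggplot2::labs(x = NULL, y = "Standardized mean difference") +
    ggplot2::theme_bw()
}
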