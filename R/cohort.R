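#' Simulation configuration for a synthetic new-user cohort
#'
#' Defines the statistical structure of a simulated two-arm new-user
#' comparative cohort: a high-dimensional sparse binary covariate layer
#' (emulating condition/drug/procedure codes), a continuous age column,
#' confounded treatment assignment through a logistic model, and survival
#' outcomes generated under proportional hazards. Negative-control outcomes
#' have hazards that depend on confounders but never on treatment, so their
#' true hazard ratio is exactly 1; a single safety outcome carries a true
#' non-null hazard ratio.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param comparator_fraction Expected fraction of subjects in the
#'   comparator arm. Default 0.25, emulating the roughly 75/25 split of a
#'   large ACEI-versus-thiazide new-user cohort.
#' @param n_binary_covariates Number of sparse binary covariates.
#' @param prevalence_range Length-2 numeric; covariate prevalences are drawn
#'   log-uniformly over this range, reproducing the long tail of rare codes
#'   seen in claims data.
#' @param n_confounders Number of covariates (the first
#'   `n_confounders` binary columns) that affect both treatment assignment
#'   and all outcome hazards. Must not exceed `n_binary_covariates`.
#' @param confounder_prevalence_range Prevalence range for the confounder
#'   subset (log-uniform); kept away from the rare tail so confounding is
#'   actually expressed in finite samples.
#' @param treatment_coefficients Log-odds effects of the confounders on
#'   treatment (length `n_confounders`). The default alternates sign with
#'   magnitudes spaced over \[0.3, 1.0\]. Set to zero for an unconfounded
#'   cohort.
#' @param outcome_coefficients Log-hazard effects of the confounders on
#'   every outcome (length `n_confounders`). Defaults to half the treatment
#'   coefficients, giving classical positive confounding.
#' @param age_treatment_coef,age_outcome_coef Per-year (centered) effects of
#'   age on treatment log-odds and outcome log-hazard.
#' @param outcome_effect_heterogeneity Half-width `h` of the uniform
#'   per-outcome scaling of the confounder-outcome effects (each outcome's
#'   log-hazard coefficients are `outcome_coefficients` times a draw from
#'   `U(1 - h, 1 + h)`). Heterogeneity across outcomes is what gives the
#'   empirical null a positive spread (`sigma > 0`); `0` makes every
#'   outcome equally confounded.
#' @param n_negative_controls Number of negative-control outcomes
#'   (default 105).
#' @param safety_outcome_true_hr True hazard ratio (> 0) of the safety
#'   outcome in the target arm; default 3, emulating an elevated angioedema
#'   risk.
#' @param baseline_hazard Baseline event rate in events per person-day;
#'   each outcome additionally receives a log-uniform rate multiplier over
#'   `outcome_rate_multiplier_range` so outcome frequencies vary.
#' @param outcome_rate_multiplier_range Length-2 range of per-outcome rate
#'   multipliers.
#' @param index_window_days Index dates are uniform over day 0 to this day.
#' @param observation_mean_days Mean of the (exponential) post-index
#'   observation duration.
#' @param days_supply Days covered by one dispensing.
#' @param refill_gap_mean Mean extra delay (geometric) between the end of
#'   one dispensing and the next; occasionally exceeds the persistence gap,
#'   ending the treatment era.
#' @param persistence_stop_prob Probability of discontinuing after each
#'   dispensing.
#' @param persistence_gap_days Maximum allowed gap between dispensings when
#'   collapsing them into a continuous-exposure era (default 30).
#' @param study_end_day Administrative end of study follow-up (day offset).
#' @param seed Integer seed; the whole cohort is reproducible given the
#'   seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 500, seed = 42)
#' cohort <- generate_cohort(cfg)
#' cohort
sim_config <- function(n_subjects,
                       comparator_fraction = 0.25,
                       n_binary_covariates = 200L,
                       prevalence_range = c(0.002, 0.3),
                       n_confounders = 20L,
                       confounder_prevalence_range = c(0.05, 0.3),
                       treatment_coefficients = NULL,
                       outcome_coefficients = NULL,
                       age_treatment_coef = 0.02,
                       age_outcome_coef = 0.01,
                       outcome_effect_heterogeneity = 0.75,
                       n_negative_controls = 105L,
                       safety_outcome_true_hr = 3,
                       baseline_hazard = 1e-4,
                       outcome_rate_multiplier_range = c(0.2, 5),
                       index_window_days = 365L,
                       observation_mean_days = 540,
                       days_supply = 30L,
                       refill_gap_mean = 5,
                       persistence_stop_prob = 0.15,
                       persistence_gap_days = 30L,
                       study_end_day = 1095L,
                       seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_binary_covariates <- as.integer(n_binary_covariates)
  n_confounders <- as.integer(n_confounders)
  n_negative_controls <- as.integer(n_negative_controls)
  if (n_subjects <= 0 || n_binary_covariates <= 0 || n_negative_controls <= 0) {
    stop_no_call("all counts in sim_config must be positive")
  }
  if (comparator_fraction <= 0 || comparator_fraction >= 1) {
    stop_no_call("comparator_fraction must lie strictly in (0, 1)")
  }
  if (n_confounders > n_binary_covariates) {
    stop_no_call("n_confounders must not exceed n_binary_covariates")
  }
  if (n_confounders < 0) stop_no_call("n_confounders must be nonnegative")
  if (length(prevalence_range) != 2 || any(prevalence_range <= 0) ||
      any(prevalence_range > 1) || diff(prevalence_range) < 0) {
    stop_no_call("prevalence_range must be an increasing pair in (0, 1]")
  }
  if (safety_outcome_true_hr <= 0) {
    stop_no_call("safety_outcome_true_hr must be positive")
  }
  if (baseline_hazard <= 0) stop_no_call("baseline_hazard must be positive")
  if (is.null(treatment_coefficients)) {
    treatment_coefficients <- if (n_confounders == 0) numeric(0) else {
      seq(0.3, 1.0, length.out = n_confounders) *
        rep_len(c(1, -1), n_confounders)
    }
  }
  if (length(treatment_coefficients) != n_confounders) {
    stop_no_call("treatment_coefficients must have length n_confounders")
  }
  if (is.null(outcome_coefficients)) {
    outcome_coefficients <- 0.5 * treatment_coefficients
  }
  if (length(outcome_coefficients) != n_confounders) {
    stop_no_call("outcome_coefficients must have length n_confounders")
  }
  cfg <- list(
    n_subjects = n_subjects,
    comparator_fraction = comparator_fraction,
    n_binary_covariates = n_binary_covariates,
    prevalence_range = prevalence_range,
    n_confounders = n_confounders,
    confounder_prevalence_range = confounder_prevalence_range,
    treatment_coefficients = treatment_coefficients,
    outcome_coefficients = outcome_coefficients,
    age_treatment_coef = age_treatment_coef,
    age_outcome_coef = age_outcome_coef,
    outcome_effect_heterogeneity = outcome_effect_heterogeneity,
    n_negative_controls = n_negative_controls,
    safety_outcome_true_hr = safety_outcome_true_hr,
    baseline_hazard = baseline_hazard,
    outcome_rate_multiplier_range = outcome_rate_multiplier_range,
    index_window_days = as.integer(index_window_days),
    observation_mean_days = observation_mean_days,
    days_supply = as.integer(days_supply),
    refill_gap_mean = refill_gap_mean,
    persistence_stop_prob = persistence_stop_prob,
    persistence_gap_days = as.integer(persistence_gap_days),
    study_end_day = as.integer(study_end_day),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic two-arm new-user cohort
#'
#' Draws covariates, assigns treatment from a logistic model in the
#' confounders (with the intercept calibrated so the marginal arm split
#' matches `comparator_fraction`), simulates dispensing-level exposure
#' records and an observation window, and generates exponential survival
#' times for every outcome under proportional hazards. Negative-control
#' hazards are identical across arms by construction; the safety-outcome
#' hazard is multiplied by `safety_outcome_true_hr` in the target arm.
#'
#' @param config A [sim_config()].
#' @return An object of class `lsc_cohort`: a list with elements
#'   `subjects` (data frame: `subject_id`, `arm`, `age`, `index_day`,
#'   `exposure_era_end_day`, `observation_end_day`), `covariates` (sparse
#'   binary matrix, rows named by subject id), `covariate_info` (covariate
#'   metadata including true simulation roles), `outcomes` (long data frame
#'   `subject_id`, `outcome_id`, `event_day`), `outcome_info`,
#'   `exposures` (dispensing-level records) and the generating `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  p <- cfg$n_binary_covariates
  nc <- cfg$n_confounders

  # covariate prevalences: log-uniform sparsity, confounders kept common
  prev <- exp(stats::runif(p, log(cfg$prevalence_range[1]),
                           log(cfg$prevalence_range[2])))
  if (nc > 0) {
    prev[seq_len(nc)] <- exp(stats::runif(
      nc, log(cfg$confounder_prevalence_range[1]),
      log(cfg$confounder_prevalence_range[2])))
  }
  if (all(prev <= 0)) stop_no_call("degenerate config: all-zero prevalence")

  cov_ids <- sprintf("c%04d", seq_len(p))
  # column-wise Bernoulli draws, assembled sparsely
  trip_i <- vector("list", p)
  for (k in seq_len(p)) {
    hits <- which(stats::runif(n) < prev[k])
    trip_i[[k]] <- hits
  }
  nnz <- lengths(trip_i)
  X <- Matrix::sparseMatrix(
    i = unlist(trip_i, use.names = FALSE),
    j = rep.int(seq_len(p), nnz),
    x = 1,
    dims = c(n, p),
    dimnames = list(as.character(seq_len(n)), cov_ids)
  )

  age <- pmin(pmax(round(stats::rnorm(n, 45, 12)), 18), 64)
  # age enters models as 5-year band indicators (the continuous value
  # stays on the subjects table); assignment and hazards below use the
  # continuous value, so the banded covariates are a coarsening of truth
  band_lo <- (age %/% 5) * 5
  band_ids <- sort(unique(band_lo))
  A <- Matrix::sparseMatrix(
    i = seq_len(n), j = match(band_lo, band_ids), x = 1,
    dims = c(n, length(band_ids)),
    dimnames = list(NULL, sprintf("age_%02d_%02d", band_ids, band_ids + 4))
  )

  # treatment assignment: logistic in the confounders, intercept calibrated
  # so the marginal target fraction equals 1 - comparator_fraction
  lp <- as.numeric(X[, seq_len(nc), drop = FALSE] %*%
                     cfg$treatment_coefficients) +
    cfg$age_treatment_coef * (age - mean(age))
  target_frac <- 1 - cfg$comparator_fraction
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + lp)) - target_frac,
    lower = -30, upper = 30, tol = 1e-10
  )$root
  arm <- ifelse(stats::runif(n) < stats::plogis(alpha + lp),
                "target", "comparator")

  index_day <- sample.int(cfg$index_window_days + 1L, n, replace = TRUE) - 1L
  # zero-day windows (disenrollment on the index day) are legal and are
  # excluded later by the minimum time-at-risk rule
  obs_days <- as.integer(round(stats::rexp(n, 1 / cfg$observation_mean_days)))
  observation_end_day <- index_day + obs_days

  disp <- simulate_dispensings(n, index_day, observation_end_day, cfg)
  exposures <- disp$exposures
  exposure_era_end_day <- pmin(as.integer(disp$era_end), observation_end_day)

  # outcomes: exponential survival under proportional hazards
  out_lp <- as.numeric(X[, seq_len(nc), drop = FALSE] %*%
                         cfg$outcome_coefficients) +
    cfg$age_outcome_coef * (age - mean(age))
  n_out <- cfg$n_negative_controls + 1L
  outcome_ids <- c(sprintf("nc_%03d", seq_len(cfg$n_negative_controls)),
                   "safety")
  mult <- exp(stats::runif(n_out, log(cfg$outcome_rate_multiplier_range[1]),
                           log(cfg$outcome_rate_multiplier_range[2])))
  # per-outcome scaling of the confounder effects: different outcomes are
  # differently susceptible to the confounders, so the systematic error of
  # negative-control estimates varies across outcomes (sigma > 0)
  conf_scale <- stats::runif(n_out, 1 - cfg$outcome_effect_heterogeneity,
                             1 + cfg$outcome_effect_heterogeneity)
  true_hr <- c(rep(1, cfg$n_negative_controls), cfg$safety_outcome_true_hr)
  horizon <- cfg$study_end_day + cfg$index_window_days + 1L
  out_list <- vector("list", n_out)
  for (o in seq_len(n_out)) {
    rate <- cfg$baseline_hazard * mult[o] * exp(out_lp * conf_scale[o]) *
      ifelse(arm == "target", true_hr[o], 1)
    t <- stats::rexp(n, rate)
    hit <- which(t <= horizon)
    out_list[[o]] <- data.frame(
      subject_id = hit,
      outcome_id = outcome_ids[o],
      event_day = index_day[hit] + as.integer(ceiling(t[hit])),
      stringsAsFactors = FALSE
    )
  }
  outcomes <- do.call(rbind, out_list)
  rownames(outcomes) <- NULL

  nb <- ncol(A)
  covariate_info <- data.frame(
    covariate_id = c(cov_ids, colnames(A)),
    type = "binary",
    prevalence = c(prev, Matrix::colMeans(A)),
    confounder = c(seq_len(p) <= nc,
                   rep(cfg$age_treatment_coef != 0, nb)),
    treatment_coef = c(cfg$treatment_coefficients, rep(0, p - nc),
                       rep(NA_real_, nb)),
    outcome_coef = c(cfg$outcome_coefficients, rep(0, p - nc),
                     rep(NA_real_, nb)),
    stringsAsFactors = FALSE
  )
  X <- cbind(X, A)
  outcome_info <- data.frame(
    outcome_id = outcome_ids,
    negative_control = c(rep(TRUE, cfg$n_negative_controls), FALSE),
    true_hr = true_hr,
    rate_multiplier = mult,
    confounder_scale = conf_scale,
    stringsAsFactors = FALSE
  )
  subjects <- data.frame(
    subject_id = seq_len(n),
    arm = arm,
    age = as.numeric(age),
    index_day = as.integer(index_day),
    exposure_era_end_day = as.integer(exposure_era_end_day),
    observation_end_day = as.integer(observation_end_day),
    stringsAsFactors = FALSE
  )
  new_cohort(subjects, X, covariate_info, outcomes, outcome_info,
             exposures, cfg)
}

# Dispensing-level exposure records: repeated fixed-length supplies with
# geometric inter-fill delays; discontinuation is geometric per fill. The
# index era end (fills collapsed under the persistence-gap rule) is tracked
# alongside: the era covering the index dispensing ends at the last fill
# before discontinuation or an uncovered gap longer than the allowance.
simulate_dispensings <- function(n, index_day, observation_end_day, cfg) {
  sid <- list(); st <- list(); en <- list()
  start <- as.numeric(index_day)
  alive <- rep(TRUE, n)
  era_alive <- rep(TRUE, n)
  era_end <- index_day + cfg$days_supply - 1
  guard <- 0L
  while (any(alive) && guard < 500L) {
    guard <- guard + 1L
    idx <- which(alive)
    sid[[guard]] <- idx
    st[[guard]] <- start[idx]
    en[[guard]] <- start[idx] + cfg$days_supply - 1
    era_end[idx[era_alive[idx]]] <- start[idx[era_alive[idx]]] + cfg$days_supply - 1
    stopnow <- stats::runif(length(idx)) < cfg$persistence_stop_prob
    delay <- stats::rgeom(length(idx), 1 / (1 + cfg$refill_gap_mean))
    nxt <- start[idx] + cfg$days_supply + delay
    past_end <- nxt > observation_end_day[idx]
    era_alive[idx[stopnow | past_end | delay > cfg$persistence_gap_days]] <- FALSE
    alive[idx[stopnow | past_end]] <- FALSE
    start[idx] <- nxt
  }
  out <- data.frame(
    subject_id = unlist(sid, use.names = FALSE),
    start_day = as.integer(unlist(st, use.names = FALSE)),
    end_day = as.integer(unlist(en, use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$subject_id, out$start_day), , drop = FALSE]
  rownames(out) <- NULL
  list(exposures = out, era_end = era_end)
}

new_cohort <- function(subjects, covariates, covariate_info, outcomes,
                       outcome_info, exposures, config) {
  rownames(covariates) <- as.character(subjects$subject_id)
  structure(
    list(subjects = subjects, covariates = covariates,
         covariate_info = covariate_info, outcomes = outcomes,
         outcome_info = outcome_info, exposures = exposures,
         config = config),
    class = "lsc_cohort"
  )
}

#' Assemble a cohort from tabular components
#'
#' Constructor for cohorts that do not come from the simulator — study
#' data read from CSVs, or small hand-built examples. Only `subjects` and
#' `covariates` are required.
#'
#' @param subjects Data frame with at least `subject_id` and `arm`
#'   (`"target"`/`"comparator"`); optional `age`, `index_day`,
#'   `exposure_era_end_day`, `observation_end_day` (dates default to a
#'   degenerate day-0 design usable for matching-only analyses).
#' @param covariates Matrix (dense or sparse) of binary covariates, one
#'   row per subject in `subjects` order, with column names.
#' @param outcomes Optional long data frame `subject_id`, `outcome_id`,
#'   `event_day`.
#' @param exposures Optional dispensing-level records (`subject_id`,
#'   `start_day`, `end_day`).
#' @return An `lsc_cohort`.
#' @export
as_cohort <- function(subjects, covariates, outcomes = NULL,
                      exposures = NULL) {
  stopifnot(all(c("subject_id", "arm") %in% names(subjects)))
  if (anyDuplicated(subjects$subject_id)) {
    stop_no_call("every subject must appear exactly once")
  }
  if (!all(subjects$arm %in% c("target", "comparator"))) {
    stop_no_call("arm must be 'target' or 'comparator'")
  }
  covariates <- methods::as(Matrix::Matrix(covariates, sparse = TRUE),
                            "generalMatrix")
  if (nrow(covariates) != nrow(subjects)) {
    stop_no_call("covariates must have one row per subject")
  }
  if (!all(covariates@x %in% c(0, 1))) {
    stop_no_call("binary covariate values must be 0 or 1")
  }
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- sprintf("c%04d", seq_len(ncol(covariates)))
  }
  has_age <- "age" %in% names(subjects)
  if (!has_age) subjects$age <- 0
  for (f in c("index_day", "exposure_era_end_day", "observation_end_day")) {
    if (is.null(subjects[[f]])) subjects[[f]] <- 0L
  }
  if (any(subjects$index_day > subjects$exposure_era_end_day |
          subjects$exposure_era_end_day > subjects$observation_end_day)) {
    stop_no_call("need index_day <= exposure_era_end_day <= ",
                 "observation_end_day for every subject")
  }
  covariate_info <- data.frame(
    covariate_id = c(colnames(covariates), if (has_age) "age"),
    type = c(rep("binary", ncol(covariates)), if (has_age) "continuous"),
    stringsAsFactors = FALSE
  )
  outcomes <- outcomes %||% data.frame(subject_id = integer(0),
                                       outcome_id = character(0),
                                       event_day = integer(0))
  outcome_info <- data.frame(
    outcome_id = unique(outcomes$outcome_id),
    stringsAsFactors = FALSE
  )
  new_cohort(subjects, covariates, covariate_info, outcomes, outcome_info,
             exposures %||% data.frame(subject_id = integer(0),
                                       start_day = integer(0),
                                       end_day = integer(0)),
             NULL)
}

#' @export
print.lsc_cohort <- function(x, ...) {
  tab <- table(x$subjects$arm)
  cat("Synthetic new-user cohort\n")
  cat(sprintf("  subjects: %d (target %d / comparator %d)\n",
              nrow(x$subjects), tab[["target"]] %||% 0L,
              tab[["comparator"]] %||% 0L))
  cat(sprintf("  binary covariates: %d; outcomes: %d (%d negative controls)\n",
              ncol(x$covariates), nrow(x$outcome_info),
              sum(x$outcome_info$negative_control)))
  invisible(x)
}

#' Arm labels of a cohort
#'
#' @param cohort An `lsc_cohort`.
#' @return Character vector named by subject id, values `"target"` /
#'   `"comparator"`.
#' @export
cohort_arms <- function(cohort) {
  stats::setNames(cohort$subjects$arm, as.character(cohort$subjects$subject_id))
}

#' Extract a covariate matrix (binary plus continuous columns)
#'
#' @param cohort An `lsc_cohort`.
#' @param covariate_ids Covariate ids to extract; default all.
#' @return A sparse matrix with one row per subject (rownames = subject id).
#' @export
covariate_matrix <- function(cohort, covariate_ids = NULL) {
  ids <- covariate_ids %||% cohort$covariate_info$covariate_id
  known <- c(cohort$covariate_info$covariate_id,
             if (!is.null(cohort$subjects$age)) "age")
  bad <- setdiff(ids, known)
  if (length(bad)) {
    stop_no_call("unknown covariate id(s): ", paste(bad, collapse = ", "))
  }
  bin <- intersect(ids, colnames(cohort$covariates))
  out <- cohort$covariates[, bin, drop = FALSE]
  if ("age" %in% ids) {
    out <- cbind(out, Matrix::Matrix(cohort$subjects$age, ncol = 1,
                                     dimnames = list(NULL, "age"),
                                     sparse = TRUE))
  }
  out[, ids, drop = FALSE]
}

#' Restrict a cohort to a subject subset
#'
#' @param cohort An `lsc_cohort`.
#' @param subject_ids Subject ids to keep (order-insensitive; the result is
#'   ordered by subject id).
#' @return An `lsc_cohort` containing only those subjects.
#' @export
subset_cohort <- function(cohort, subject_ids) {
  ids <- sort(unique(as.integer(subject_ids)))
  keep <- cohort$subjects$subject_id %in% ids
  if (sum(keep) != length(ids)) {
    stop_no_call("subject_ids contains ids absent from the cohort")
  }
  new_cohort(
    cohort$subjects[keep, , drop = FALSE],
    cohort$covariates[as.character(ids), , drop = FALSE],
    cohort$covariate_info,
    cohort$outcomes[cohort$outcomes$subject_id %in% ids, , drop = FALSE],
    cohort$outcome_info,
    cohort$exposures[cohort$exposures$subject_id %in% ids, , drop = FALSE],
    cohort$config
  )
}

#' Draw stratified subsamples of a cohort
#'
#' Each draw samples `floor(fraction * arm size)` subjects from every arm
#' without replacement (sampling is stratified by comparison group), so the
#' within-draw arm ratio matches the parent cohort up to integer
#' truncation. Draws are independent, each on its own seeded substream.
#'
#' @param cohort An `lsc_cohort`.
#' @param fraction Sampling fraction in (0, 1].
#' @param n_draws Number of independent draws.
#' @param seed Integer master seed for the draw substreams.
#' @return A list of `lsc_cohort` objects of length `n_draws`.
#' @export
draw_subsamples <- function(cohort, fraction, n_draws, seed = 1L) {
  if (fraction <= 0 || fraction > 1) {
    stop_no_call("fraction must lie in (0, 1]")
  }
  n_draws <- as.integer(n_draws)
  arms <- cohort_arms(cohort)
  by_arm <- split(cohort$subjects$subject_id, cohort$subjects$arm)
  take <- vapply(by_arm, function(ids) floor(fraction * length(ids)),
                 numeric(1))
  if (any(take < 1)) {
    stop_no_call("fraction ", fraction, " yields an empty arm")
  }
  lapply(seq_len(n_draws), function(d) {
    with_seed(derive_seed(seed, "subsample", d), {
      picked <- unlist(lapply(names(by_arm), function(a) {
        sample(by_arm[[a]], take[[a]])
      }), use.names = FALSE)
      subset_cohort(cohort, picked)
    })
  })
}

#' Write / read a cohort as plain-text CSV files
#'
#' The on-disk layout is `subjects.csv`, `covariates.csv`
#' (subject_id/covariate_id/value triplets), `covariate_info.csv`,
#' `outcomes.csv`, `outcome_info.csv` and `exposures.csv` in `dir`.
#'
#' @param cohort An `lsc_cohort`.
#' @param dir Directory to write to (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns an
#'   `lsc_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trip <- Matrix::summary(cohort$covariates)
  trip_df <- data.frame(
    subject_id = cohort$subjects$subject_id[trip$i],
    covariate_id = colnames(cohort$covariates)[trip$j],
    value = trip$x, stringsAsFactors = FALSE
  )
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(trip_df, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariate_info, file.path(dir, "covariate_info.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcome_info, file.path(dir, "outcome_info.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$exposures, file.path(dir, "exposures.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  trip <- utils::read.csv(file.path(dir, "covariates.csv"),
                          stringsAsFactors = FALSE)
  covariate_info <- utils::read.csv(file.path(dir, "covariate_info.csv"),
                                    stringsAsFactors = FALSE)
  bin_ids <- covariate_info$covariate_id[covariate_info$type == "binary"]
  row_idx <- match(trip$subject_id, subjects$subject_id)
  col_idx <- match(trip$covariate_id, bin_ids)
  X <- Matrix::sparseMatrix(
    i = row_idx, j = col_idx, x = trip$value,
    dims = c(nrow(subjects), length(bin_ids)),
    dimnames = list(as.character(subjects$subject_id), bin_ids)
  )
  new_cohort(
    subjects, X, covariate_info,
    utils::read.csv(file.path(dir, "outcomes.csv"), stringsAsFactors = FALSE),
    utils::read.csv(file.path(dir, "outcome_info.csv"),
                    stringsAsFactors = FALSE),
    utils::read.csv(file.path(dir, "exposures.csv"), stringsAsFactors = FALSE),
    NULL
  )
}
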