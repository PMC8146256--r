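#' Cardinality-matching configuration
#'
#' @param balance_criterion Nonnegative maximum absolute post-match
#'   standardized mean difference per matching covariate. `0` requests
#'   exact marginal distributional balance (fine balance); 0.01, 0.05 and
#'   0.10 are conventional settings.
#' @param solver_time_limit Solver wall-clock limit in seconds (default
#'   60; `NULL` for no limit). When the limit is reached without a matched
#'   sample of size >= 1, the result is flagged infeasible rather than
#'   silently relaxed — consider loosening the balance criterion.
#' @param solver_gap_tolerance Relative MIP gap; the default 0 requires a
#'   proven optimum.
#' @param seed Seed recorded for provenance (the solve itself is
#'   deterministic).
#' @return An object of class `cm_config`.
#' @export
cm_config <- function(balance_criterion, solver_time_limit = 60,
                      solver_gap_tolerance = 0, seed = 1L) {
  if (balance_criterion < 0) {
    stop_no_call("balance_criterion must be nonnegative")
  }
  structure(list(balance_criterion = balance_criterion,
                 solver_time_limit = solver_time_limit,
                 solver_gap_tolerance = solver_gap_tolerance,
                 seed = as.integer(seed)),
            class = "cm_config")
}

#' Build the cardinality-matching integer program
#'
#' Selection formulation: one binary indicator per subject (selected into
#' the matched sample or not), maximizing the matched-sample size `n`
#' subject to equal selected counts in both arms and, for every matching
#' covariate `k` with positive pre-match pooled standard deviation
#' `s_pk`, the linearized balance constraint
#' `|sum_target v - sum_comparator v| <= criterion * s_pk * n`
#' (two linear inequalities; `n` is itself the sum of target indicators,
#' so everything stays linear). With `balance_criterion = 0` the
#' constraints collapse to equal matched covariate sums — fine balance.
#' Covariates with zero pre-match pooled SD are excluded from the
#' constraints. Subjects with identical rows over the constrained
#' covariates are interchangeable, so the program is aggregated to one
#' integer variable per distinct covariate pattern per arm; this is exact
#' and is what keeps large cohorts tractable.
#'
#' @param cohort An `lsc_cohort`.
#' @param matching_covariate_ids Covariates to constrain (typically
#'   [extract_matching_covariates()] output). An empty set yields an
#'   unconstrained maximum-size problem, with a warning.
#' @param config A [cm_config()].
#' @return An object of class `cm_problem`.
#' @export
build_cm_problem <- function(cohort, matching_covariate_ids, config) {
  stopifnot(inherits(config, "cm_config"))
  arms <- cohort_arms(cohort)
  ids_t <- cohort$subjects$subject_id[arms == "target"]
  ids_c <- cohort$subjects$subject_id[arms == "comparator"]
  if (!length(ids_t) || !length(ids_c)) {
    stop_no_call("both arms must be nonempty")
  }
  if (!length(matching_covariate_ids)) {
    warning("empty matching-covariate set: solving an unconstrained ",
            "maximum-size problem")
    V <- matrix(0, nrow(cohort$subjects), 0)
    rownames(V) <- as.character(cohort$subjects$subject_id)
    s_p <- numeric(0)
  } else {
    V <- as.matrix(covariate_matrix(cohort, matching_covariate_ids))
    s_p <- vapply(seq_len(ncol(V)), function(k) {
      pooled_sd(V[as.character(ids_t), k], V[as.character(ids_c), k])
    }, numeric(1))
    names(s_p) <- colnames(V)
    keep <- which(s_p > 0)
    if (length(keep) < ncol(V)) {
      V <- V[, keep, drop = FALSE]
    }
    s_p <- s_p[keep]
  }
  delta <- config$balance_criterion * s_p

  agg <- function(ids) {
    M <- V[as.character(ids), , drop = FALSE]
    key <- if (ncol(M)) apply(M, 1, paste, collapse = "\r") else
      rep("", length(ids))
    idx <- split(seq_along(ids), key)
    idx <- idx[order(names(idx))]
    list(
      patterns = do.call(rbind, lapply(idx, function(r) M[r[1], , drop = TRUE])),
      counts = lengths(idx),
      ids = lapply(idx, function(r) sort(ids[r]))
    )
  }
  structure(
    list(target = agg(ids_t), comparator = agg(ids_c),
         covariate_ids = colnames(V), pooled_sd = s_p, delta = delta,
         config = config,
         n_target = length(ids_t), n_comparator = length(ids_c)),
    class = "cm_problem"
  )
}

#' @export
print.cm_problem <- function(x, ...) {
  cat("Cardinality-matching problem\n")
  cat(sprintf("  subjects: %d target / %d comparator (%d + %d patterns)\n",
              x$n_target, x$n_comparator,
              length(x$target$counts), length(x$comparator$counts)))
  cat(sprintf("  constrained covariates: %d; balance criterion: %g\n",
              length(x$covariate_ids), x$config$balance_criterion))
  invisible(x)
}

#' Solve a cardinality-matching problem
#'
#' Maximizes the matched-sample size with the configured balance
#' constraints via the MILP backend, expands the optimal pattern counts to
#' concrete subjects (lowest ids within a pattern, deterministically) and
#' rank-pairs the two selected sets.
#'
#' @param problem A `cm_problem` from [build_cm_problem()].
#' @param scores Optional propensity scores named by subject id, used to
#'   rank-pair the selected sets (i-th ranked target with i-th ranked
#'   comparator). Without scores, pairing falls back to subject-id order;
#'   the downstream unconditional analysis is invariant to the pairing.
#' @return A `match_result` with `method = "cm"`; `feasible` is `FALSE`
#'   (with zero pairs) when no matched sample of size >= 1 satisfies the
#'   constraints or the solver stopped without an incumbent.
#' @export
solve_cardinality_match <- function(problem, scores = NULL) {
  stopifnot(inherits(problem, "cm_problem"))
  cfg <- problem$config
  Pt <- problem$target; Pc <- problem$comparator
  nt <- length(Pt$counts); nc <- length(Pc$counts)
  K <- length(problem$covariate_ids)
  obj <- c(rep(1, nt), rep(0, nc))
  # rows: size equality, then per covariate the two linearized inequalities
  A <- matrix(0, 1 + 2 * K, nt + nc)
  A[1, ] <- c(rep(1, nt), rep(-1, nc))
  lower <- c(0, rep(-Inf, 2 * K))
  upper_con <- c(0, rep(NA_real_, 2 * K))
  if (K > 0) {
    Vt <- matrix(Pt$patterns, nrow = nt, ncol = K)
    Vc <- matrix(Pc$patterns, nrow = nc, ncol = K)
    for (k in seq_len(K)) {
      r1 <- 2 * k; r2 <- 2 * k + 1
      # sum_t v - sum_c v - delta_k * n <= 0
      A[r1, ] <- c(Vt[, k] - problem$delta[k], -Vc[, k])
      upper_con[r1] <- 0
      # -(sum_t v - sum_c v) - delta_k * n <= 0
      A[r2, ] <- c(-Vt[, k] - problem$delta[k], Vc[, k])
      upper_con[r2] <- 0
    }
  }
  upper_con[is.na(upper_con)] <- 0
  sol <- solve_milp_max(obj, A, lower, upper_con,
                        upper = c(Pt$counts, Pc$counts),
                        time_limit = cfg$solver_time_limit,
                        rel_gap = cfg$solver_gap_tolerance)
  stats <- list(status = sol$status, gap = sol$gap,
                n_variables = nt + nc, n_constraints = 1 + 2 * K,
                n_patterns_target = nt, n_patterns_comparator = nc)
  empty <- data.frame(target_id = integer(0), comparator_id = integer(0))
  settings <- list(balance_criterion = cfg$balance_criterion,
                   solver_gap_tolerance = cfg$solver_gap_tolerance)
  if (is.null(sol$x) || sol$objective < 1) {
    return(match_result(empty, "cm", settings, feasible = FALSE,
                        stats = stats))
  }
  take <- function(agg, counts) {
    unlist(mapply(function(ids, m) ids[seq_len(m)], agg$ids,
                  as.integer(round(counts)), SIMPLIFY = FALSE),
           use.names = FALSE)
  }
  sel_t <- take(Pt, sol$x[seq_len(nt)])
  sel_c <- take(Pc, sol$x[nt + seq_len(nc)])
  pairs <- pair_selected(sel_t, sel_c, scores)
  match_result(pairs, "cm", settings, feasible = TRUE, stats = stats)
}

#' Pair two selected sets by propensity-score rank
#'
#' The i-th ranked target (by score, ties by id) is paired with the i-th
#' ranked comparator. Any pairing of the same selected sets yields the
#' same unconditional downstream estimate; rank pairing is a deterministic
#' convention.
#'
#' @param selected_target,selected_comparator Equal-length subject-id
#'   vectors.
#' @param scores Optional scores named by subject id; `NULL` falls back to
#'   id order.
#' @return Data frame of `target_id`, `comparator_id`.
#' @export
pair_selected <- function(selected_target, selected_comparator,
                          scores = NULL) {
  if (length(selected_target) != length(selected_comparator)) {
    stop_no_call("selected sets must have equal size")
  }
  rank_by <- function(ids) {
    if (is.null(scores)) return(sort(ids))
    ids[order(scores[as.character(ids)], ids)]
  }
  data.frame(target_id = as.integer(rank_by(selected_target)),
             comparator_id = as.integer(rank_by(selected_comparator)))
}

#' One-call cardinality matching
#'
#' Convenience wrapper: builds and solves the program.
#'
#' @inheritParams build_cm_problem
#' @inheritParams solve_cardinality_match
#' @export
cardinality_match <- function(cohort, matching_covariate_ids, config,
                              scores = NULL) {
  problem <- build_cm_problem(cohort, matching_covariate_ids, config)
  solve_cardinality_match(problem, scores)
}
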