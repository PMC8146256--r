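#' Pre-match pooled standard deviation of a covariate
#'
#' Unweighted two-group form `sqrt((s2_target + s2_comparator) / 2)` with
#' per-group sample variances (n - 1 denominator).
#'
#' @param values_target,values_comparator Covariate values per arm.
#' @return Nonnegative pooled SD (0 when both groups are constant).
#' @export
pooled_sd <- function(values_target, values_comparator) {
  v1 <- stats::var(values_target)
  v2 <- stats::var(values_comparator)
  if (is.na(v1)) v1 <- 0
  if (is.na(v2)) v2 <- 0
  sqrt((v1 + v2) / 2)
}

#' Standardized mean difference
#'
#' `SMD = (mean_target - mean_comparator) / s_p`, where `s_p` is the
#' pre-match pooled standard deviation. Post-match SMDs are computed on
#' matched subjects but always against the pre-match `s_p`, so matching is
#' judged on the original covariate scale.
#'
#' @param values_target,values_comparator Covariate values in each group.
#' @param pooled_sd_prematch Pre-match pooled SD; must be positive (a zero
#'   SD yields an undefined SMD, which callers flag and exclude).
#' @return Signed SMD.
#' @export
compute_smd <- function(values_target, values_comparator,
                        pooled_sd_prematch) {
  if (!is.finite(pooled_sd_prematch) || pooled_sd_prematch <= 0) {
    stop_no_call("pooled_sd_prematch must be positive; zero-variance ",
                 "covariates have undefined SMDs")
  }
  (mean(values_target) - mean(values_comparator)) / pooled_sd_prematch
}

#' Covariate balance table
#'
#' One row per covariate: per-arm means, pre-match pooled SD and SMD.
#' When `match` is supplied, means are computed on the matched subjects
#' only (stage `"post"`) while the pooled SD stays pre-match. Covariates
#' with zero pre-match pooled SD get `smd = NA` and `defined = FALSE`;
#' they are excluded from summaries rather than counted as balanced.
#'
#' @param cohort An `lsc_cohort` (the pre-match sample defining `s_p`).
#' @param match A `match_result`, or `NULL` for a pre-match table.
#' @param covariate_ids Covariates in scope (candidate or matching set).
#' @param draw_id Optional identifier recorded on the report.
#' @return A data frame of class `balance_report` with attributes `stage`
#'   and `draw_id`.
#' @export
balance_table <- function(cohort, match = NULL, covariate_ids,
                          draw_id = NA) {
  arms <- cohort_arms(cohort)
  X <- covariate_matrix(cohort, covariate_ids)
  pre_t <- rownames(X)[arms == "target"]
  pre_c <- rownames(X)[arms == "comparator"]
  s_p <- vapply(seq_along(covariate_ids), function(k) {
    pooled_sd(X[pre_t, k], X[pre_c, k])
  }, numeric(1))
  if (is.null(match)) {
    rows_t <- pre_t; rows_c <- pre_c; stage <- "pre"
  } else {
    rows_t <- as.character(match$pairs$target_id)
    rows_c <- as.character(match$pairs$comparator_id)
    stage <- "post"
  }
  m_t <- if (length(rows_t)) Matrix::colMeans(X[rows_t, , drop = FALSE]) else
    rep(NA_real_, ncol(X))
  m_c <- if (length(rows_c)) Matrix::colMeans(X[rows_c, , drop = FALSE]) else
    rep(NA_real_, ncol(X))
  defined <- s_p > 0 & length(rows_t) > 0 & length(rows_c) > 0
  out <- data.frame(
    covariate_id = covariate_ids,
    mean_target = as.numeric(m_t),
    mean_comparator = as.numeric(m_c),
    pooled_sd_prematch = s_p,
    smd = ifelse(defined, (as.numeric(m_t) - as.numeric(m_c)) / s_p,
                 NA_real_),
    defined = defined,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, stage = stage, draw_id = draw_id,
            class = c("balance_report", "data.frame"))
}

#' Count imbalanced covariates in a balance report
#'
#' A covariate is balanced when `|SMD| < threshold` strictly; entries at
#' or above the threshold count as imbalanced. Undefined entries are
#' excluded from both numerator and denominator.
#'
#' @param report A `balance_report` (or any data frame with `smd`).
#' @param threshold Balance threshold; conventionally 0.10.
#' @return List with `count`, `proportion` and `n_defined`.
#' @export
count_imbalanced <- function(report, threshold = 0.10) {
  if (nrow(report) == 0) stop_no_call("empty balance report")
  smd <- report$smd[!is.na(report$smd)]
  list(count = sum(abs(smd) >= threshold),
       proportion = if (length(smd)) mean(abs(smd) >= threshold) else NA_real_,
       n_defined = length(smd))
}

#' Pool balance reports across subsample draws
#'
#' Concatenates the per-draw SMDs into one joint distribution (covariate
#' balance assessed across all draws considered jointly) and summarizes
#' it: mean and max absolute SMD, SD of SMDs, joint imbalance count and
#' proportion, and the per-draw average imbalance count/proportion.
#'
#' @param reports List of `balance_report`s with a common stage.
#' @param threshold Balance threshold passed to [count_imbalanced()].
#' @return List with `pooled` (the concatenated report, draw ids attached)
#'   and `summary`.
#' @export
pool_reports <- function(reports, threshold = 0.10) {
  stopifnot(length(reports) >= 1)
  stages <- vapply(reports, function(r) attr(r, "stage"), character(1))
  if (length(unique(stages)) != 1) {
    stop_no_call("reports must share the same stage to be pooled")
  }
  pooled <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- as.data.frame(reports[[i]])
    r$draw_id <- attr(reports[[i]], "draw_id") %||% i
    r
  }))
  smd <- pooled$smd[!is.na(pooled$smd)]
  per_draw <- lapply(reports, count_imbalanced, threshold = threshold)
  summary <- list(
    n_smd = length(smd),
    mean_abs_smd = mean(abs(smd)),
    sd_smd = stats::sd(smd),
    max_abs_smd = if (length(smd)) max(abs(smd)) else NA_real_,
    imbalanced_count = sum(abs(smd) >= threshold),
    imbalanced_proportion = if (length(smd)) mean(abs(smd) >= threshold)
      else NA_real_,
    mean_imbalanced_count_per_draw =
      mean(vapply(per_draw, `[[`, numeric(1), "count")),
    mean_imbalanced_proportion_per_draw =
      mean(vapply(per_draw, `[[`, numeric(1), "proportion"), na.rm = TRUE)
  )
  list(pooled = pooled, summary = summary)
}
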