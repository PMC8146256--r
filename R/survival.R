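#' Collapse dispensing records into continuous-exposure eras
#'
#' Successive dispensings are merged into one era when the uncovered gap
#' between them (days from the end of one supply to the start of the next,
#' exclusive) is at most `gap_days`.
#'
#' @param start_day,end_day Integer vectors of dispensing intervals
#'   (inclusive), assumed sorted by `start_day`.
#' @param gap_days Maximum allowed uncovered gap (default 30).
#' @return Data frame of era `start_day` / `end_day`.
#' @export
collapse_exposure_eras <- function(start_day, end_day, gap_days = 30L) {
  stopifnot(length(start_day) == length(end_day))
  if (!length(start_day)) {
    return(data.frame(start_day = integer(0), end_day = integer(0)))
  }
  o <- order(start_day)
  start_day <- start_day[o]; end_day <- end_day[o]
  es <- start_day[1]; ee <- end_day[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start_day)[-1]) {
    if (start_day[i] - ee - 1L <= gap_days) {
      ee <- max(ee, end_day[i])
    } else {
      out_s <- c(out_s, es); out_e <- c(out_e, ee)
      es <- start_day[i]; ee <- end_day[i]
    }
  }
  data.frame(start_day = c(out_s, es), end_day = c(out_e, ee))
}

#' Intention-to-treat time-at-risk construction
#'
#' Subjects are followed from day 1 post-index to the earliest of the
#' administrative study end, the end of continuous exposure under a
#' persistence window allowing at most `persistence_gap_days` between
#' dispensings, and the end of continuous observation. Subjects with fewer
#' than `min_days` days at risk are excluded (and counted).
#'
#' When the cohort carries dispensing-level `exposures`, era ends are
#' recomputed from them under `persistence_gap_days`; otherwise the stored
#' `exposure_era_end_day` is used.
#'
#' @param cohort An `lsc_cohort`.
#' @param persistence_gap_days Persistence window (default 30).
#' @param study_end_day Administrative end of follow-up; defaults to the
#'   cohort's generating configuration.
#' @param min_days Minimum required days at risk (default 1).
#' @return Data frame of class `time_at_risk`: `subject_id`, `arm`,
#'   `start_day`, `end_day`, `days`; attribute `n_excluded` records the
#'   minimum-time exclusions.
#' @export
build_time_at_risk <- function(cohort, persistence_gap_days = 30L,
                               study_end_day = NULL, min_days = 1L) {
  s <- cohort$subjects
  study_end_day <- study_end_day %||% cohort$config$study_end_day
  if (is.null(study_end_day)) {
    stop_no_call("study_end_day must be given when the cohort carries no ",
                 "generating configuration")
  }
  era_end <- if (!is.null(cohort$exposures) && nrow(cohort$exposures)) {
    ends <- s$exposure_era_end_day
    sp_s <- split(cohort$exposures$start_day, cohort$exposures$subject_id)
    sp_e <- split(cohort$exposures$end_day, cohort$exposures$subject_id)
    idx <- match(as.character(s$subject_id), names(sp_s))
    for (i in seq_len(nrow(s))) {
      if (is.na(idx[i])) next
      eras <- collapse_exposure_eras(sp_s[[idx[i]]], sp_e[[idx[i]]],
                                     persistence_gap_days)
      hit <- which(eras$start_day <= s$index_day[i] &
                     eras$end_day >= s$index_day[i])
      if (length(hit)) ends[i] <- eras$end_day[hit[1]]
    }
    pmin(ends, s$observation_end_day)
  } else {
    s$exposure_era_end_day
  }
  start <- s$index_day + 1L
  end <- pmin(study_end_day, era_end, s$observation_end_day)
  days <- end - start + 1L
  keep <- days >= min_days
  out <- data.frame(
    subject_id = s$subject_id[keep],
    arm = s$arm[keep],
    start_day = start[keep],
    end_day = end[keep],
    days = days[keep],
    stringsAsFactors = FALSE
  )
  structure(out, n_excluded = sum(!keep),
            class = c("time_at_risk", "data.frame"))
}

#' Unconditional Cox proportional-hazards effect estimate
#'
#' Fits a treatment-only Cox model (Efron tie handling) for one outcome on
#' a time-at-risk table: the first event of the outcome inside a subject's
#' at-risk window is an event at that day; otherwise the subject is
#' censored at the window end. Matched pairs are treated as an analytic
#' cohort — the model is unconditional, so the estimate depends only on
#' the selected subjects, not on who is paired with whom.
#'
#' @param tar A `time_at_risk` table (optionally restricted to matched
#'   subjects, possibly stacked across draws).
#' @param outcomes Long outcome table (`subject_id`, `outcome_id`,
#'   `event_day`), e.g. `cohort$outcomes`.
#' @param outcome_id Outcome to analyze.
#' @return One-row data frame (`outcome_id`, `log_hr`, `se`, `n_events`,
#'   `n_events_target`, `n_events_comparator`, `estimable`). Estimates are
#'   flagged non-estimable when either arm has no events (monotone partial
#'   likelihood) and `log_hr`/`se` are `NA`.
#' @export
fit_cox <- function(tar, outcomes, outcome_id) {
  ev <- outcomes[outcomes$outcome_id == outcome_id, c("subject_id",
                                                      "event_day")]
  ev <- ev[order(ev$subject_id, ev$event_day), , drop = FALSE]
  ev <- ev[!duplicated(ev$subject_id), , drop = FALSE]
  eday <- ev$event_day[match(tar$subject_id, ev$subject_id)]
  has_event <- !is.na(eday) & eday >= tar$start_day & eday <= tar$end_day
  time <- ifelse(has_event, eday - tar$start_day + 1L, tar$days)
  n_t <- sum(has_event & tar$arm == "target")
  n_c <- sum(has_event & tar$arm == "comparator")
  base <- data.frame(outcome_id = outcome_id, log_hr = NA_real_,
                     se = NA_real_, n_events = n_t + n_c,
                     n_events_target = n_t, n_events_comparator = n_c,
                     estimable = FALSE, stringsAsFactors = FALSE)
  if (n_t == 0 || n_c == 0) return(base)
  treat <- as.integer(tar$arm == "target")
  # monotone-likelihood fits (coefficient drifting to +/- infinity) are
  # flagged non-estimable below rather than surfaced as a coxph warning
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, has_event) ~ treat,
                    ties = "efron"))
  beta <- unname(stats::coef(fit)[1])
  se <- unname(sqrt(diag(fit$var))[1])
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 50) {
    return(base)
  }
  base$log_hr <- beta; base$se <- se; base$estimable <- TRUE
  base
}

#' Fit unconditional Cox models for a set of outcomes
#'
#' @inheritParams fit_cox
#' @param outcome_ids Outcomes to fit (default: all negative controls
#'   would be a typical choice).
#' @return Data frame with one row per outcome (see [fit_cox()]).
#' @export
fit_outcome_models <- function(tar, outcomes, outcome_ids) {
  do.call(rbind, lapply(outcome_ids, function(o) fit_cox(tar, outcomes, o)))
}
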