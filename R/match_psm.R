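#' Matched-sample result container
#'
#' Shared by propensity-score matching and cardinality matching.
#'
#' @param pairs Data frame with columns `target_id`, `comparator_id`.
#' @param method `"psm"` or `"cm"`.
#' @param settings Named list echoing the matching configuration.
#' @param feasible Logical; `FALSE` when a cardinality-matching solve found
#'   no matched sample of size >= 1 (or exhausted its limits without an
#'   incumbent).
#' @param stats Optional named list of solver/matching statistics.
#' @return An object of class `match_result`.
#' @export
match_result <- function(pairs, method, settings = list(), feasible = TRUE,
                         stats = list()) {
  stopifnot(is.data.frame(pairs),
            all(c("target_id", "comparator_id") %in% names(pairs)))
  if (anyDuplicated(pairs$target_id) || anyDuplicated(pairs$comparator_id)) {
    stop_no_call("a subject appears in more than one pair")
  }
  structure(list(pairs = pairs, method = method, settings = settings,
                 feasible = feasible, stats = stats),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Match result (%s): %d pairs%s\n", x$method, nrow(x$pairs),
              if (x$feasible) "" else " [infeasible]"))
  if (length(x$settings)) {
    cat("  settings: ",
        paste(names(x$settings),
              vapply(x$settings, function(v) paste(format(v), collapse = ","),
                     character(1)),
              sep = "=", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Matched subject ids
#'
#' @param match A `match_result`.
#' @return Integer vector of all subject ids in the matched sample.
#' @export
matched_ids <- function(match) {
  as.integer(c(match$pairs$target_id, match$pairs$comparator_id))
}

#' Caliper width on the logit propensity-score scale
#'
#' The caliper is `caliper_fraction` times the pooled standard deviation of
#' the logit scores, where the pooled SD is the unweighted two-group form
#' `sqrt((s2_target + s2_comparator) / 2)` computed on the pre-match
#' scores.
#'
#' @param scores Propensity scores in (0, 1), named by subject id.
#' @param arms Arm labels named by subject id (`"target"`/`"comparator"`).
#' @param caliper_fraction Positive fraction of the pooled logit SD
#'   (0.10 and 0.20 are conventional settings).
#' @return Caliper width on the logit scale.
#' @export
compute_caliper <- function(scores, arms, caliper_fraction) {
  stopifnot(caliper_fraction > 0)
  arms <- arms[names(scores)]
  if (!all(c("target", "comparator") %in% arms)) {
    stop_no_call("both arms must be nonempty")
  }
  if (any(scores <= 0 | scores >= 1)) {
    stop_no_call("scores must lie strictly in (0, 1)")
  }
  l <- logit(scores)
  s2 <- tapply(l, arms, stats::var)
  pooled <- sqrt((s2[["target"]] + s2[["comparator"]]) / 2)
  if (!is.finite(pooled) || pooled == 0) {
    stop_no_call("degenerate scores: pooled logit SD is zero")
  }
  caliper_fraction * pooled
}

#' Greedy 1:1 propensity-score matching within a caliper
#'
#' Units of the smaller arm are processed in a seeded random permutation;
#' each takes the still-unmatched opposite-arm unit with the smallest
#' absolute logit-score difference, provided that difference lies within
#' the caliper (ties broken by smallest subject id). Matching is without
#' replacement and unmatched units are dropped.
#'
#' @inheritParams compute_caliper
#' @param caliper_fraction Caliper as a fraction of the pooled logit SD.
#' @param seed Seed for the processing-order permutation.
#' @return A `match_result` with `method = "psm"`.
#' @export
greedy_match <- function(scores, arms, caliper_fraction = 0.1, seed = 1L) {
  caliper <- compute_caliper(scores, arms, caliper_fraction)
  arms <- arms[names(scores)]
  l <- logit(scores)
  ids <- as.integer(names(scores))
  tgt <- which(arms == "target")
  cmp <- which(arms == "comparator")
  if (length(tgt) <= length(cmp)) {
    from <- tgt; to <- cmp; from_is_target <- TRUE
  } else {
    from <- cmp; to <- tgt; from_is_target <- FALSE
  }
  order_from <- with_seed(derive_seed(seed, "greedy_order"),
                          sample(from))
  # opposite arm kept sorted by (logit, id) with an availability mask; the
  # nearest available neighbor is the first available position on either
  # side of the insertion point (distance is monotone moving outward)
  ord <- order(l[to], ids[to])
  to_l <- l[to][ord]
  to_id <- ids[to][ord]
  n_to <- length(to)
  avail <- rep(TRUE, n_to)
  res_from <- integer(length(order_from))
  res_to <- integer(length(order_from))
  n_pairs <- 0L
  tie_tol <- 1e-12
  smallest_id_in_tied_run <- function(k, dir) {
    # among available entries sharing to_l[k] (scanning in direction dir),
    # return the one with the smallest subject id
    best <- k
    j <- k + dir
    while (j >= 1L && j <= n_to && abs(to_l[j] - to_l[k]) <= tie_tol) {
      if (avail[j] && to_id[j] < to_id[best]) best <- j
      j <- j + dir
    }
    best
  }
  for (u in order_from) {
    x <- l[u]
    j <- findInterval(x, to_l)
    lo <- j; hi <- j + 1L
    while (lo >= 1L && !avail[lo]) lo <- lo - 1L
    while (hi <= n_to && !avail[hi]) hi <- hi + 1L
    if (lo < 1L && hi > n_to) next
    dlo <- if (lo >= 1L) x - to_l[lo] else Inf
    dhi <- if (hi <= n_to) to_l[hi] - x else Inf
    best <- if (dlo < dhi - tie_tol) {
      smallest_id_in_tied_run(lo, -1L)
    } else if (dhi < dlo - tie_tol) {
      smallest_id_in_tied_run(hi, 1L)
    } else {
      a <- smallest_id_in_tied_run(lo, -1L)
      b <- smallest_id_in_tied_run(hi, 1L)
      if (to_id[a] < to_id[b]) a else b
    }
    if (min(dlo, dhi) <= caliper) {
      avail[best] <- FALSE
      n_pairs <- n_pairs + 1L
      res_from[n_pairs] <- u
      res_to[n_pairs] <- best
    }
  }
  res_from <- res_from[seq_len(n_pairs)]
  res_to <- res_to[seq_len(n_pairs)]
  pairs <- if (from_is_target) {
    data.frame(target_id = ids[res_from], comparator_id = to_id[res_to])
  } else {
    data.frame(target_id = to_id[res_to], comparator_id = ids[res_from])
  }
  match_result(pairs, method = "psm",
               settings = list(caliper_fraction = caliper_fraction,
                               caliper = caliper, seed = seed),
               stats = list(n_from = length(from), n_to = length(to),
                            n_matched = nrow(pairs)))
}

#' Write matched pairs as CSV with a JSON settings sidecar
#'
#' @param match A `match_result`.
#' @param path CSV path; settings go to `paste0(path, ".json")`.
#' @export
write_match_result <- function(match, path) {
  utils::write.csv(match$pairs, path, row.names = FALSE)
  jsonlite::write_json(
    list(method = match$method, feasible = match$feasible,
         settings = match$settings, stats = match$stats),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
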