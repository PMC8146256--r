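#' Heuristic candidate-covariate selection by frequency
#'
#' Candidate covariates are those observed with overall frequency strictly
#' greater than `min_frequency` (fraction of subjects, both arms combined,
#' with a non-zero value). Continuous covariates such as age are observed
#' for every subject and therefore always pass any threshold below 1.
#'
#' @param cohort An `lsc_cohort`.
#' @param min_frequency Frequency threshold in `[0, 1)`; the conventional
#'   large-scale default is 0.001 (0.1%).
#' @return Character vector of covariate ids.
#' @export
select_candidate_covariates <- function(cohort, min_frequency = 0.001) {
  if (nrow(cohort$subjects) == 0) stop_no_call("empty cohort")
  if (min_frequency < 0 || min_frequency >= 1) {
    stop_no_call("min_frequency must lie in [0, 1)")
  }
  X <- covariate_matrix(cohort)
  freq <- Matrix::colMeans(X != 0)
  names(freq)[freq > min_frequency]
}

#' Fit a regularized (LASSO) propensity model
#'
#' L1-penalized logistic regression of treatment arm on the candidate
#' covariates, with the regularization strength chosen by k-fold
#' cross-validated binomial deviance over a seeded fold assignment.
#' Continuous covariates are standardized (centered/scaled) before
#' penalization; binary covariates enter as 0/1. The L1 path produces
#' exact zeros, so the non-zero coefficient set is well defined.
#'
#' @param cohort An `lsc_cohort`.
#' @param candidates Candidate covariate ids (see
#'   [select_candidate_covariates()]); must be nonempty.
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `propensity_model` with elements `intercept`,
#'   `coefficients` (named, sparse in the sense that most are exactly 0),
#'   `regularization_strength` (selected lambda), `candidate_covariate_ids`,
#'   `cv_folds`, and the continuous-covariate scaling used.
#' @export
fit_propensity_model <- function(cohort, candidates, cv_folds = 10L,
                                 seed = 1L) {
  if (length(candidates) == 0) stop_no_call("candidates must be nonempty")
  arm <- cohort$subjects$arm
  if (min(table(factor(arm, c("target", "comparator")))) < 2) {
    stop_no_call("need at least 2 subjects per arm")
  }
  X <- covariate_matrix(cohort, candidates)
  info <- cohort$covariate_info
  cont <- intersect(candidates,
                    info$covariate_id[info$type == "continuous"])
  centers <- stats::setNames(numeric(length(cont)), cont)
  scales <- stats::setNames(rep(1, length(cont)), cont)
  for (cc in cont) {
    v <- as.numeric(X[, cc])
    centers[cc] <- mean(v)
    s <- stats::sd(v)
    scales[cc] <- if (s > 0) s else 1
    X[, cc] <- (v - centers[cc]) / scales[cc]
  }
  y <- as.integer(arm == "target")
  foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), length(y))))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          nfolds = cv_folds, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  lambda <- cv$lambda.min
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(X))
  lp_range <- max(abs(beta[1] + as.numeric(X %*% beta[-1])))
  if (!is.finite(lp_range) || lp_range > 30) {
    warning("possible separation in the propensity fit; ",
            "returning the model at the strongest penalty on the path")
    lambda <- max(cv$lambda)
    beta <- as.numeric(stats::coef(cv, s = lambda))
    names(beta) <- c("(Intercept)", colnames(X))
  }
  structure(
    list(intercept = unname(beta[1]),
         coefficients = beta[-1],
         regularization_strength = lambda,
         candidate_covariate_ids = candidates,
         cv_folds = as.integer(cv_folds),
         seed = as.integer(seed),
         continuous_centers = centers,
         continuous_scales = scales),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (L1-penalized logistic regression)\n")
  cat(sprintf("  candidates: %d; non-zero coefficients: %d\n",
              length(x$candidate_covariate_ids),
              sum(x$coefficients != 0)))
  cat(sprintf("  lambda: %.6g (selected by %d-fold CV deviance)\n",
              x$regularization_strength, x$cv_folds))
  invisible(x)
}

#' Predict propensity scores
#'
#' Inverse-logit of the fitted linear predictor; continuous covariates are
#' transformed with the scaling stored in the model, so scores are
#' comparable across cohorts (e.g. a model fitted on one draw applied to
#' another).
#'
#' @param model A `propensity_model`.
#' @param cohort An `lsc_cohort` containing the model's candidate
#'   covariates.
#' @return Numeric vector of scores in (0, 1), named by subject id.
#' @export
predict_scores <- function(model, cohort) {
  stopifnot(inherits(model, "propensity_model"))
  X <- covariate_matrix(cohort, model$candidate_covariate_ids)
  for (cc in names(model$continuous_centers)) {
    X[, cc] <- (as.numeric(X[, cc]) - model$continuous_centers[cc]) /
      model$continuous_scales[cc]
  }
  lp <- model$intercept +
    as.numeric(X %*% model$coefficients[colnames(X)])
  stats::setNames(stats::plogis(lp),
                  as.character(cohort$subjects$subject_id))
}

#' Matching covariates: candidates with non-zero propensity coefficients
#'
#' The empirical matching-covariate set used by cardinality matching is
#' defined as the candidate covariates whose L1-penalized coefficient is
#' exactly non-zero as stored (coordinate descent yields exact zeros, so no
#' epsilon threshold is applied).
#'
#' @param model A `propensity_model`.
#' @return Character vector of covariate ids (possibly empty).
#' @export
extract_matching_covariates <- function(model) {
  stopifnot(inherits(model, "propensity_model"))
  names(model$coefficients)[model$coefficients != 0]
}

#' Serialize / restore a propensity model as JSON
#'
#' Only non-zero coefficients are stored.
#'
#' @param model A `propensity_model`.
#' @param path File path.
#' @export
write_propensity_model <- function(model, path) {
  nz <- model$coefficients[model$coefficients != 0]
  obj <- list(
    intercept = model$intercept,
    coefficients = as.list(nz),
    regularization_strength = model$regularization_strength,
    candidate_covariate_ids = model$candidate_covariate_ids,
    cv_folds = model$cv_folds,
    seed = model$seed,
    continuous_centers = as.list(model$continuous_centers),
    continuous_scales = as.list(model$continuous_scales)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_propensity_model
#' @export
read_propensity_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- stats::setNames(rep(0, length(obj$candidate_covariate_ids)),
                           obj$candidate_covariate_ids)
  nz <- unlist(obj$coefficients)
  coefs[names(nz)] <- nz
  structure(
    list(intercept = obj$intercept,
         coefficients = coefs,
         regularization_strength = obj$regularization_strength,
         candidate_covariate_ids = obj$candidate_covariate_ids,
         cv_folds = obj$cv_folds,
         seed = obj$seed,
         continuous_centers = unlist(obj$continuous_centers) %||%
           stats::setNames(numeric(0), character(0)),
         continuous_scales = unlist(obj$continuous_scales) %||%
           stats::setNames(numeric(0), character(0))),
    class = "propensity_model"
  )
}
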