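test_that("frequency-based candidate selection matches a direct count oracle", {
  co <- confounded_cohort()
  X <- covariate_matrix(co)
  freq <- Matrix::colMeans(X != 0)

  for (thr in c(0, 0.001, 0.02, 0.2)) {
    expect_setequal(select_candidate_covariates(co, thr),
                    names(freq)[freq > thr])
  }
  # strict inequality at the threshold: one carrier in 2000 is 0.0005
  one_carrier <- names(freq)[abs(freq - 1 / 2000) < 1e-12]
  if (length(one_carrier)) {
    expect_false(any(one_carrier %in%
                       select_candidate_covariates(co, 0.001)))
  }
  expect_error(select_candidate_covariates(co, 1), "min_frequency")
})

test_that("LASSO shrinks null predictors to zero and keeps a strong confounder", {
  arm <- rep(c("target", "comparator"), c(6000, 2000))
  set.seed(41)
  conf <- rbinom(8000, 1, ifelse(arm == "target", 0.62, 0.38))
  noise <- rbinom(8000, 1, 0.5)
  co <- toy_cohort(arm, cbind(conf = conf, noise = noise))
  m <- fit_propensity_model(co, c("conf", "noise"), seed = 4)
  expect_gt(m$coefficients[["conf"]], 0)
  # oracle: unpenalized fit agrees in sign and dominates in magnitude
  glm_fit <- glm(I(arm == "target") ~ conf + noise, family = binomial)
  expect_gt(coef(glm_fit)[["conf"]], m$coefficients[["conf"]])
  expect_lt(abs(m$coefficients[["noise"]]),
            abs(m$coefficients[["conf"]]) / 5)
  # matching covariates are exactly the non-zero set
  expect_setequal(extract_matching_covariates(m),
                  names(m$coefficients)[m$coefficients != 0])
})

test_that("model fitting is deterministic given the seed", {
  co <- confounded_cohort()
  cand <- select_candidate_covariates(co, 0.01)
  m1 <- fit_propensity_model(co, cand, seed = 8)
  m2 <- fit_propensity_model(co, cand, seed = 8)
  expect_identical(m1$regularization_strength, m2$regularization_strength)
  expect_identical(m1$coefficients, m2$coefficients)
})

test_that("scores are the inverse-logit of the linear predictor", {
  co <- toy_cohort(c("target", "comparator", "target"),
                   matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
                          dimnames = list(NULL, c("a", "b"))))
  m <- structure(list(
    intercept = log(3), coefficients = c(a = 0.5, b = -1),
    candidate_covariate_ids = c("a", "b"),
    continuous_centers = setNames(numeric(0), character(0)),
    continuous_scales = setNames(numeric(0), character(0))),
    class = "propensity_model")
  sc <- predict_scores(m, co)
  expect_equal(unname(sc),
               plogis(log(3) + c(0.5, -1, -0.5)))
  # intercept-only model gives a constant score
  m$coefficients[] <- 0
  expect_equal(unname(predict_scores(m, co)), rep(0.75, 3))
  m$intercept <- 0
  expect_equal(unname(predict_scores(m, co)), rep(0.5, 3))
})

test_that("scores are invariant to subject ordering", {
  co <- confounded_cohort()
  cand <- select_candidate_covariates(co, 0.01)
  m <- fit_propensity_model(co, cand, seed = 2)
  sc <- predict_scores(m, co)
  perm <- sample(co$subjects$subject_id)
  co_perm <- subset_cohort(co, perm)
  sc_perm <- predict_scores(m, co_perm)
  expect_equal(sc_perm[names(sc)], sc)
})

test_that("raising the frequency threshold nests the candidates and thins the matching set", {
  co <- confounded_cohort()
  thresholds <- c(0.001, 0.02, 0.1)
  cands <- lapply(thresholds, function(thr) {
    select_candidate_covariates(co, thr)
  })
  # candidate sets are nested as the threshold rises
  expect_true(all(cands[[2]] %in% cands[[1]]))
  expect_true(all(cands[[3]] %in% cands[[2]]))
  # a much stricter threshold yields fewer matching covariates (individual
  # refits in between need not be monotone: the cross-validated penalty is
  # re-tuned on each candidate set)
  sizes <- vapply(cands, function(cand) {
    m <- fit_propensity_model(co, cand, seed = 6)
    length(extract_matching_covariates(m))
  }, numeric(1))
  expect_lt(sizes[3], sizes[1])
  expect_lte(sizes[3], length(cands[[3]]))
})

test_that("known confounders with adequate prevalence enter the matching set", {
  co <- generate_cohort(sim_config(
    n_subjects = 6000, n_binary_covariates = 30, n_confounders = 4,
    treatment_coefficients = c(1, -1, 0.9, -0.9),
    confounder_prevalence_range = c(0.2, 0.4),
    n_negative_controls = 2, seed = 17))
  cand <- select_candidate_covariates(co, 0.001)
  m <- fit_propensity_model(co, cand, seed = 17)
  expect_true(all(sprintf("c%04d", 1:4) %in%
                    extract_matching_covariates(m)))
})

test_that("propensity model JSON round-trip preserves the model", {
  co <- confounded_cohort()
  cand <- select_candidate_covariates(co, 0.02)
  m <- fit_propensity_model(co, cand, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_propensity_model(m, path)
  back <- read_propensity_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients[names(m$coefficients)], m$coefficients)
  expect_equal(predict_scores(back, co), predict_scores(m, co))
})
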