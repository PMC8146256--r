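cm_toy <- function(arm, X) {
  toy_cohort(arm, X)
}

test_that("identical covariate rows across arms match completely", {
  X <- matrix(rep(c(1, 0, 1), 2), 6, 1, dimnames = list(NULL, "v"))
  co <- cm_toy(rep(c("target", "comparator"), each = 3), X)
  for (crit in c(0, 0.05, 0.1)) {
    m <- cardinality_match(co, "v", cm_config(crit))
    expect_true(m$feasible)
    expect_equal(nrow(m$pairs), 3)
  }
})

test_that("fine balance on the 4v4 single-covariate instance yields the enumerated optimum of 3", {
  X <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0), 8, 1,
              dimnames = list(NULL, "v"))
  co <- cm_toy(rep(c("target", "comparator"), each = 4), X)
  m <- cardinality_match(co, "v", cm_config(0))
  expect_true(m$feasible)
  expect_equal(nrow(m$pairs), 3)
  # matched sums are equal: one covariate-positive pair, two negative
  bt <- balance_table(co, m, "v")
  expect_equal(bt$smd, 0)
})

test_that("the ILP objective equals exhaustive enumeration on random small instances", {
  set.seed(99)
  for (rep in 1:12) {
    nt <- sample(3:6, 1); nc <- sample(3:6, 1)
    K <- sample(1:3, 1)
    X <- matrix(rbinom((nt + nc) * K, 1, runif(1, 0.2, 0.8)), nt + nc, K,
                dimnames = list(NULL, paste0("v", seq_len(K))))
    crit <- sample(c(0, 0.05, 0.1, 0.5), 1)
    co <- cm_toy(rep(c("target", "comparator"), c(nt, nc)), X)
    s_p <- vapply(seq_len(K), function(k) {
      pooled_sd(X[seq_len(nt), k], X[nt + seq_len(nc), k])
    }, numeric(1))
    m <- cardinality_match(co, colnames(X), cm_config(crit))
    expect_equal(nrow(m$pairs),
                 cm_enumeration_optimum(X[seq_len(nt), , drop = FALSE],
                                        X[nt + seq_len(nc), , drop = FALSE],
                                        crit, s_p),
                 info = sprintf("instance %d (criterion %g)", rep, crit))
  }
})

test_that("post-match SMDs respect the criterion and retention is monotone in it", {
  co <- confounded_cohort()
  cand <- select_candidate_covariates(co, 0.02)
  ps <- fit_propensity_model(co, cand, seed = 21)
  mcov <- extract_matching_covariates(ps)
  scores <- predict_scores(ps, co)
  sizes <- c()
  for (crit in c(0.10, 0.05, 0.01, 0)) {
    m <- cardinality_match(co, mcov, cm_config(crit), scores = scores)
    expect_true(m$feasible)
    bt <- balance_table(co, m, mcov)
    expect_lte(max(abs(bt$smd[bt$defined])), crit + 1e-9)
    sizes <- c(sizes, nrow(m$pairs))
  }
  expect_true(all(diff(sizes) <= 0))
  # comparator arm fully retained at the loosest criterion: every
  # comparator can be balanced here
  expect_equal(sizes[1], sum(co$subjects$arm == "comparator"))
})

test_that("problem construction: delta scaling, zero-SD exclusion, constraint count", {
  X <- cbind(v1 = rep(c(1, 0), 5), v2 = rep(1, 10))
  co <- cm_toy(rep(c("target", "comparator"), each = 5), X)
  p <- build_cm_problem(co, c("v1", "v2"), cm_config(0.10))
  # constant covariate excluded from constraints
  expect_equal(p$covariate_ids, "v1")
  expect_equal(unname(p$delta), 0.10 * unname(p$pooled_sd))
  # one binary covariate with s_p ~ 0.527 here: delta per matched unit
  expect_equal(unname(p$pooled_sd),
               sqrt((var(X[1:5, 1]) + var(X[6:10, 1])) / 2))
})

test_that("an empty matching set warns and returns the unconstrained maximum", {
  co <- cm_toy(rep(c("target", "comparator"), c(4, 3)),
               matrix(rbinom(7, 1, 0.5), 7, 1, dimnames = list(NULL, "v")))
  expect_warning(m <- cardinality_match(co, character(0), cm_config(0.1)),
                 "unconstrained")
  expect_equal(nrow(m$pairs), 3)
})

test_that("rank pairing is a bijection and the Cox estimate ignores the pairing", {
  co <- generate_cohort(sim_config(
    n_subjects = 1500, n_binary_covariates = 20, n_confounders = 4,
    n_negative_controls = 5, seed = 33))
  cand <- select_candidate_covariates(co, 0.02)
  ps <- fit_propensity_model(co, cand, seed = 33)
  scores <- predict_scores(ps, co)
  m <- cardinality_match(co, extract_matching_covariates(ps),
                         cm_config(0.05), scores = scores)
  expect_true(m$feasible)
  expect_equal(anyDuplicated(unlist(m$pairs)), 0L)

  tar <- build_time_at_risk(co)
  tar_m <- tar[tar$subject_id %in% matched_ids(m), ]
  est1 <- fit_cox(tar_m, co$outcomes, "nc_001")
  # permute the pairing of the same selected sets: estimate is unchanged
  perm <- m
  perm$pairs$comparator_id <- sample(perm$pairs$comparator_id)
  tar_p <- tar[tar$subject_id %in% matched_ids(perm), ]
  est2 <- fit_cox(tar_p, co$outcomes, "nc_001")
  expect_equal(est1$log_hr, est2$log_hr)
  expect_equal(est1$se, est2$se)
})

test_that("singleton selected sets pair directly", {
  expect_equal(pair_selected(4L, 9L, NULL),
               data.frame(target_id = 4L, comparator_id = 9L))
  sc <- setNames(c(0.2, 0.8, 0.5, 0.6), 1:4)
  p <- pair_selected(c(1L, 2L), c(3L, 4L), sc)
  expect_equal(p, data.frame(target_id = c(1L, 2L),
                             comparator_id = c(3L, 4L)))
})
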