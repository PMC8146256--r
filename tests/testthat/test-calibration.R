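sim_null_estimates <- function(n, mu, sigma, tau_range, seed) {
  set.seed(seed)
  tau <- runif(n, tau_range[1], tau_range[2])
  beta <- rnorm(n, mu, sigma)
  data.frame(log_hr = rnorm(n, beta, tau), se = tau, estimable = TRUE)
}

test_that("closed-form E|beta| matches Monte Carlo across a (mu, sigma) grid", {
  set.seed(31)
  for (mu in c(-0.5, 0, 0.1, 0.3)) {
    for (sigma in c(0.05, 0.2, 1)) {
      draws <- abs(rnorm(2e5, mu, sigma))
      mc_se <- sd(draws) / sqrt(length(draws))
      expect_lt(abs(expected_systematic_error(list(mu = mu, sigma = sigma)) -
                      mean(draws)),
                3 * mc_se)
    }
  }
  # degenerate limits
  expect_equal(expected_systematic_error(list(mu = 0, sigma = 0)), 0)
  expect_equal(expected_systematic_error(list(mu = 0.3, sigma = 0)), 0.3)
  expect_equal(expected_systematic_error(list(mu = 0.3, sigma = 1e-4)), 0.3,
               tolerance = 1e-6)
  expect_equal(expected_systematic_error(list(mu = 0, sigma = 1)),
               sqrt(2 / pi), tolerance = 1e-12)
})

test_that("ESE is nondecreasing in sigma and in |mu|", {
  sig <- seq(0, 1, by = 0.1)
  ese_sig <- vapply(sig, function(s) {
    expected_systematic_error(list(mu = 0.2, sigma = s))
  }, numeric(1))
  expect_true(all(diff(ese_sig) >= -1e-12))
  mus <- seq(0, 1, by = 0.1)
  ese_mu <- vapply(mus, function(m) {
    expected_systematic_error(list(mu = m, sigma = 0.3))
  }, numeric(1))
  expect_true(all(diff(ese_mu) >= -1e-12))
})

test_that("the empirical-null MLE matches a dense grid search", {
  est <- sim_null_estimates(20, 0.15, 0.25, c(0.05, 0.3), seed = 51)
  fit <- fit_null_mle(est)
  grid <- null_grid_mle(est$log_hr, est$se,
                        seq(-0.5, 0.8, by = 0.002),
                        seq(0, 0.8, by = 0.002))
  expect_lt(abs(fit$mu - grid["mu"]), 0.003)      # grid spacing 0.002
  expect_lt(abs(fit$sigma - grid["sigma"]), 0.003)
})

test_that("estimates symmetric around zero give mu near zero", {
  theta <- c(-0.4, -0.2, -0.1, 0.1, 0.2, 0.4)
  fit <- fit_null_mle(theta, se = rep(0.05, 6))
  expect_equal(fit$mu, 0, tolerance = 1e-4)
})

test_that("parameter recovery improves with the number of negative controls", {
  errs <- vapply(c(20, 100, 500), function(n) {
    est <- sim_null_estimates(n, 0.1, 0.2, c(0.05, 0.3), seed = 42)
    fit <- fit_null_mle(est)
    abs(fit$mu - 0.1) + abs(fit$sigma - 0.2)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  # at 500 controls both parameters are recovered within 10% relative error
  est <- sim_null_estimates(500, 0.1, 0.2, c(0.05, 0.3), seed = 42)
  fit <- fit_null_mle(est)
  expect_lt(abs(fit$mu - 0.1) / 0.1, 0.10)
  expect_lt(abs(fit$sigma - 0.2) / 0.2, 0.10)
})

test_that("non-estimable rows are dropped with their count recorded", {
  est <- sim_null_estimates(10, 0, 0.1, c(0.1, 0.2), seed = 3)
  est$estimable[c(2, 5)] <- FALSE
  est$log_hr[2] <- NA
  fit <- suppressWarnings(fit_null_mle(est))
  expect_equal(fit$n_used, 8)
  expect_equal(fit$n_dropped, 2)
  expect_error(fit_null_mle(est[1:2, ]), "at least 2")
})

test_that("MCMC credible intervals are seeded, concentrate with data, and match quadrature", {
  est <- sim_null_estimates(20, 0.1, 0.2, c(0.05, 0.2), seed = 61)
  r1 <- ese_credible_interval(est, iterations = 4000, burn_in = 1000,
                              seed = 9)
  r2 <- ese_credible_interval(est, iterations = 4000, burn_in = 1000,
                              seed = 9)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_identical(r1$ci_high, r2$ci_high)
  expect_gte(r1$acceptance_rate, 0.1)
  expect_lte(r1$acceptance_rate, 0.6)
  # posterior mode consistent with the MLE; interval brackets the point
  expect_lte(r1$ci_low, r1$point)
  expect_gte(r1$ci_high, r1$point)

  # independent fine-grid posterior quadrature on the same instance
  quad <- ese_quadrature_ci(est$log_hr, est$se,
                            mu_lim = c(-0.3, 0.5),
                            lsig_lim = log(c(0.01, 1)))
  expect_lt(abs(r1$ci_low - quad[1]), 0.025)
  expect_lt(abs(r1$ci_high - quad[2]), 0.025)

  # tighter data shrink the interval toward the point estimate
  tight <- sim_null_estimates(400, 0.1, 0.2, c(0.01, 0.05), seed = 62)
  rt <- ese_credible_interval(tight, iterations = 4000, burn_in = 1000,
                              seed = 9)
  expect_lt(rt$ci_high - rt$ci_low, r1$ci_high - r1$ci_low)
})

test_that("calibration identities: degenerate null and centered estimate", {
  null0 <- structure(list(mu = 0, sigma = 0), class = "systematic_error_model")
  cal <- calibrate_estimate(null0, log_hr = 0.4, se = 0.1)
  expect_equal(cal$log_hr, 0.4)
  expect_equal(cal$se, 0.1)
  expect_equal(cal$p, cal$uncalibrated$p)
  expect_equal(cal$ci_low, cal$uncalibrated$ci_low)

  null1 <- structure(list(mu = 0.25, sigma = 0.1),
                     class = "systematic_error_model")
  cal2 <- calibrate_estimate(null1, log_hr = 0.25, se = 0.2)
  expect_equal(cal2$p, 1)
  expect_equal(cal2$log_hr, 0)
  expect_equal(cal2$se, sqrt(0.1^2 + 0.2^2))
})

test_that("calibrated p-values restore nominal type-I error under injected systematic error", {
  # fit the null on 100 controls, then calibrate 1000 fresh null outcomes
  # drawn from the same systematic-error process
  fit <- fit_null_mle(sim_null_estimates(100, 0.2, 0.1, c(0.05, 0.15),
                                         seed = 71))
  fresh <- sim_null_estimates(1000, 0.2, 0.1, c(0.05, 0.15), seed = 72)
  ps <- vapply(seq_len(1000), function(i) {
    cal <- calibrate_estimate(fit, fresh$log_hr[i], fresh$se[i])
    c(cal$p, cal$uncalibrated$p)
  }, numeric(2))
  cal_rate <- mean(ps[1, ] < 0.05)
  uncal_rate <- mean(ps[2, ] < 0.05)
  expect_lt(abs(cal_rate - 0.05), 0.03)
  expect_gt(uncal_rate, 0.25)
})
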