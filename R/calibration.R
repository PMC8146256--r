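# Empirical-null systematic error model from negative-control estimates.
#
# Each negative-control log hazard ratio estimate theta_hat_i is modeled as
#   theta_hat_i ~ N(theta_i + beta_i, tau_i^2),   theta_i = 0 (true HR 1)
#   beta_i     ~ N(mu, sigma^2)
# so marginally theta_hat_i ~ N(mu, sigma^2 + tau_i^2). The fitted (mu,
# sigma) summarize residual systematic error; E|beta| is the expected
# systematic error (ESE).

null_loglik <- function(mu, sigma, theta_hat, tau) {
  sum(stats::dnorm(theta_hat, mean = mu, sd = sqrt(sigma^2 + tau^2),
                   log = TRUE))
}

#' Fit the empirical-null systematic error model by maximum likelihood
#'
#' Maximizes the marginal likelihood of the negative-control estimates
#' over (mu, sigma) with sigma constrained nonnegative. Non-estimable
#' estimates (rows with `estimable = FALSE` or missing values) are dropped
#' with their count recorded.
#'
#' @param estimates Data frame with columns `log_hr` and `se` (e.g. from
#'   [fit_outcome_models()] on negative controls), or a numeric vector of
#'   log hazard ratios with `se` supplied separately.
#' @param se Standard errors when `estimates` is a numeric vector.
#' @return An object of class `systematic_error_model` with elements `mu`,
#'   `sigma`, `loglik`, `n_used`, `n_dropped` and `boundary` (`TRUE` when
#'   the sigma estimate hit the zero boundary).
#' @export
fit_null_mle <- function(estimates, se = NULL) {
  est <- normalize_estimates(estimates, se)
  if (est$n_used < 2) {
    stop_no_call("need at least 2 estimable negative-control estimates")
  }
  theta <- est$log_hr; tau <- est$se
  nll <- function(par) -null_loglik(par[1], par[2], theta, tau)
  start <- c(mean(theta), max(stats::sd(theta), 0.01))
  fit <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(-Inf, 0), upper = c(Inf, Inf))
  boundary <- fit$par[2] <= 1e-8
  if (boundary) {
    warning("sigma estimate at the zero boundary")
  }
  structure(
    list(mu = fit$par[1], sigma = max(fit$par[2], 0),
         loglik = -fit$value, n_used = est$n_used,
         n_dropped = est$n_dropped, boundary = boundary),
    class = "systematic_error_model"
  )
}

normalize_estimates <- function(estimates, se = NULL) {
  if (is.data.frame(estimates)) {
    ok <- if ("estimable" %in% names(estimates)) estimates$estimable else TRUE
    ok <- ok & is.finite(estimates$log_hr) & is.finite(estimates$se) &
      estimates$se > 0
    list(log_hr = estimates$log_hr[ok], se = estimates$se[ok],
         n_used = sum(ok), n_dropped = sum(!ok))
  } else {
    stopifnot(length(estimates) == length(se))
    ok <- is.finite(estimates) & is.finite(se) & se > 0
    list(log_hr = estimates[ok], se = se[ok],
         n_used = sum(ok), n_dropped = sum(!ok))
  }
}

#' @export
print.systematic_error_model <- function(x, ...) {
  cat("Empirical-null systematic error model\n")
  cat(sprintf("  mu = %.4f, sigma = %.4f (fit on %d estimates, %d dropped)\n",
              x$mu, x$sigma, x$n_used, x$n_dropped))
  cat(sprintf("  expected systematic error: %.4f\n",
              expected_systematic_error(x)))
  invisible(x)
}

#' Expected systematic error (mean absolute bias under the fitted null)
#'
#' `E|beta|` for `beta ~ N(mu, sigma^2)` — the mean of the folded normal:
#' `sigma * sqrt(2/pi) * exp(-mu^2 / (2 sigma^2)) + mu * (1 - 2 * pnorm(-mu / sigma))`,
#' reducing to `|mu|` when `sigma = 0`.
#'
#' @param model A `systematic_error_model`, or a list with `mu`, `sigma`.
#' @return Nonnegative scalar ESE.
#' @export
expected_systematic_error <- function(model) {
  mu <- model$mu; sigma <- model$sigma
  if (sigma <= 0) return(abs(mu))
  sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
}

#' ESE with 95% credible interval via Markov-chain Monte Carlo
#'
#' Random-walk Metropolis over `(mu, log sigma)` targeting the marginal
#' likelihood of the negative-control estimates with flat priors on
#' `(mu, log sigma)`. The proposal SD is adapted toward a 20-50%
#' acceptance rate during burn-in and frozen afterwards. The ESE is
#' computed for every retained posterior sample; the interval is the
#' 2.5/97.5 percentile range.
#'
#' @inheritParams fit_null_mle
#' @param iterations Post-burn-in iterations (default 10000).
#' @param burn_in Burn-in iterations (default 1000).
#' @param seed Seed for the chain.
#' @return An object of class `ese_result`: `point` (ESE at the MLE),
#'   `ci_low`, `ci_high`, `acceptance_rate`, `model` (the MLE fit) and the
#'   posterior `samples` (matrix of mu, sigma, ese).
#' @export
ese_credible_interval <- function(estimates, se = NULL, iterations = 10000L,
                                  burn_in = 1000L, seed = 1L) {
  est <- normalize_estimates(estimates, se)
  if (est$n_used < 2) {
    stop_no_call("need at least 2 estimable negative-control estimates")
  }
  mle <- fit_null_mle(estimates, se)
  theta <- est$log_hr; tau <- est$se
  logpost <- function(mu, lsig) null_loglik(mu, exp(lsig), theta, tau)
  draw <- with_seed(derive_seed(seed, "ese_mcmc"), {
    cur <- c(mle$mu, log(max(mle$sigma, 1e-3)))
    cur_lp <- logpost(cur[1], cur[2])
    step <- c(0.1, 0.25)
    total <- burn_in + iterations
    out <- matrix(NA_real_, iterations, 2)
    acc_win <- 0L; win <- 0L; acc_post <- 0L
    for (it in seq_len(total)) {
      prop <- cur + stats::rnorm(2) * step
      prop_lp <- logpost(prop[1], prop[2])
      if (is.finite(prop_lp) &&
          log(stats::runif(1)) < prop_lp - cur_lp) {
        cur <- prop; cur_lp <- prop_lp
        acc_win <- acc_win + 1L
        if (it > burn_in) acc_post <- acc_post + 1L
      }
      win <- win + 1L
      if (it <= burn_in && win == 50L) {
        rate <- acc_win / win
        if (rate < 0.2) step <- step * 0.7
        if (rate > 0.5) step <- step * 1.4
        acc_win <- 0L; win <- 0L
      }
      if (it > burn_in) out[it - burn_in, ] <- cur
    }
    list(samples = out, acceptance = acc_post / iterations)
  })
  if (draw$acceptance < 0.1 || draw$acceptance > 0.6) {
    warning(sprintf("MCMC acceptance rate %.2f outside [0.1, 0.6]",
                    draw$acceptance))
  }
  mu_s <- draw$samples[, 1]
  sig_s <- exp(draw$samples[, 2])
  ese_s <- vapply(seq_along(mu_s), function(i) {
    expected_systematic_error(list(mu = mu_s[i], sigma = sig_s[i]))
  }, numeric(1))
  ci <- unname(stats::quantile(ese_s, c(0.025, 0.975)))
  structure(
    list(point = expected_systematic_error(mle),
         ci_low = ci[1], ci_high = ci[2],
         acceptance_rate = draw$acceptance,
         model = mle,
         samples = cbind(mu = mu_s, sigma = sig_s, ese = ese_s),
         iterations = as.integer(iterations),
         burn_in = as.integer(burn_in), seed = as.integer(seed)),
    class = "ese_result"
  )
}

#' @export
print.ese_result <- function(x, ...) {
  cat(sprintf("ESE = %.3f [95%% CrI: (%.3f, %.3f)]\n",
              x$point, x$ci_low, x$ci_high))
  invisible(x)
}

#' Calibrate an effect estimate against the empirical null
#'
#' The calibrated p-value is the two-sided tail probability of the
#' observed log hazard ratio under `N(mu, sigma^2 + tau^2)` — the null
#' distribution that negative-control estimates actually follow. The
#' calibrated point estimate shifts out the mean bias
#' (`log_hr - mu`) and the calibrated standard error inflates to
#' `sqrt(sigma^2 + tau^2)`, with a symmetric normal confidence interval.
#' With a degenerate null (`mu = 0`, `sigma = 0`) the calibrated
#' statistics equal the uncalibrated ones.
#'
#' @param model A `systematic_error_model`.
#' @param log_hr Observed log hazard ratio (theta-hat).
#' @param se Its standard error (tau).
#' @param level Confidence level (default 0.95).
#' @return List with `log_hr`, `se`, `ci_low`, `ci_high`, `p` (all
#'   calibrated, on the log-HR scale) and the `uncalibrated` equivalents.
#' @export
calibrate_estimate <- function(model, log_hr, se, level = 0.95) {
  stopifnot(inherits(model, "systematic_error_model"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  cal_se <- sqrt(model$sigma^2 + se^2)
  cal <- log_hr - model$mu
  p_cal <- 2 * stats::pnorm(-abs(log_hr - model$mu) / cal_se)
  list(
    log_hr = cal, se = cal_se,
    ci_low = cal - z * cal_se, ci_high = cal + z * cal_se,
    p = p_cal,
    uncalibrated = list(
      log_hr = log_hr, se = se,
      ci_low = log_hr - z * se, ci_high = log_hr + z * se,
      p = 2 * stats::pnorm(-abs(log_hr) / se)
    )
  )
}
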