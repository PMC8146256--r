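# Shared fixtures and independent oracles, all built in code.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

# mid-sized confounded cohort shared across matching/balance tests
confounded_cohort <- function() {
  cached("confounded", generate_cohort(sim_config(
    n_subjects = 2000, n_binary_covariates = 60, n_confounders = 10,
    n_negative_controls = 20, seed = 101
  )))
}

# hand-built cohort: arms and binary covariate rows given directly
toy_cohort <- function(arm, X, age = NULL, index_day = NULL,
                       era_end = NULL, obs_end = NULL, outcomes = NULL) {
  n <- length(arm)
  subjects <- data.frame(subject_id = seq_len(n), arm = arm)
  if (!is.null(age)) subjects$age <- age
  if (!is.null(index_day)) subjects$index_day <- index_day
  if (!is.null(era_end)) subjects$exposure_era_end_day <- era_end
  if (!is.null(obs_end)) subjects$observation_end_day <- obs_end
  as_cohort(subjects, X, outcomes = outcomes)
}

# --- independent oracles -------------------------------------------------

# exhaustive cardinality-matching optimum: largest s such that some pair of
# size-s subsets meets |sum_t v - sum_c v| <= criterion * s_p * s for all
# constrained covariates
cm_enumeration_optimum <- function(Vt, Vc, criterion, s_p) {
  nt <- nrow(Vt); nc <- nrow(Vc)
  keep <- which(s_p > 0)
  best <- 0L
  for (s in seq_len(min(nt, nc))) {
    tol <- criterion * s_p[keep] * s + 1e-9
    subs_t <- utils::combn(nt, s, simplify = FALSE)
    subs_c <- utils::combn(nc, s, simplify = FALSE)
    sums_c <- lapply(subs_c, function(b) colSums(Vc[b, keep, drop = FALSE]))
    feasible <- FALSE
    for (a in subs_t) {
      sa <- colSums(Vt[a, keep, drop = FALSE])
      for (sb in sums_c) {
        if (all(abs(sa - sb) <= tol)) { feasible <- TRUE; break }
      }
      if (feasible) break
    }
    if (feasible) best <- s
  }
  best
}

# Efron-tie log partial likelihood for a treatment-only Cox model,
# maximized by golden-section search: the dual route to survival::coxph
efron_loglik <- function(beta, time, event, z) {
  r <- exp(beta * z)
  ll <- 0
  for (t in sort(unique(time[event]))) {
    D <- which(event & time == t)
    R <- which(time >= t)
    d <- length(D)
    sD <- sum(r[D]); sR <- sum(r[R])
    ll <- ll + beta * sum(z[D]) -
      sum(vapply(seq_len(d) - 1, function(j) log(sR - (j / d) * sD),
                 numeric(1)))
  }
  ll
}

efron_mle <- function(time, event, z) {
  stats::optimize(function(b) efron_loglik(b, time, event, z),
                  interval = c(-8, 8), maximum = TRUE,
                  tol = 1e-8)$maximum
}

# dense grid maximizer of the empirical-null marginal likelihood
null_grid_mle <- function(theta, tau, mu_grid, sigma_grid) {
  ll <- outer(mu_grid, sigma_grid, Vectorize(function(mu, sg) {
    sum(stats::dnorm(theta, mu, sqrt(sg^2 + tau^2), log = TRUE))
  }))
  idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  c(mu = mu_grid[idx[1]], sigma = sigma_grid[idx[2]])
}

# posterior quadrature over (mu, log sigma) with flat priors; returns the
# 2.5/97.5 weighted percentiles of the implied ESE
ese_quadrature_ci <- function(theta, tau, mu_lim, lsig_lim, n_grid = 160) {
  mu_g <- seq(mu_lim[1], mu_lim[2], length.out = n_grid)
  ls_g <- seq(lsig_lim[1], lsig_lim[2], length.out = n_grid)
  ll <- outer(mu_g, ls_g, Vectorize(function(mu, ls) {
    sum(stats::dnorm(theta, mu, sqrt(exp(2 * ls) + tau^2), log = TRUE))
  }))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  ese <- outer(mu_g, ls_g, Vectorize(function(mu, ls) {
    expected_systematic_error(list(mu = mu, sigma = exp(ls)))
  }))
  o <- order(ese)
  cw <- cumsum(w[o])
  c(ese[o][which.max(cw >= 0.025)], ese[o][which.max(cw >= 0.975)])
}
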