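---
title: "Large-scale matched cohort design: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Large-scale matched cohort design: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lscmatch` supports a complete workflow for two-arm observational
comparative cohort studies: empirical selection of matching covariates,
two matching algorithms (greedy propensity-score matching and
optimization-based cardinality matching), covariate balance diagnostics,
quantification of residual confounding with negative-control outcomes,
and calibration of effect estimates against the resulting empirical
null. This vignette documents the underlying models, the package's
numerical choices, and the design decisions that were genuinely open.

## The study design being modeled

The intended setting is a *new-user, active-comparator* cohort: subjects
initiate one of two treatments (the `target` or `comparator` arm) at an
index date, carry a high-dimensional vector of mostly-rare binary
covariates measured before index (conditions, drug exposures,
procedures, demographics), and are followed for survival outcomes.
Because treatment choice is confounded, the analytic sample is
restricted to a 1:1 matched subset before outcome models are fitted.

## Propensity model and matching covariates

Candidate covariates are those with observed frequency strictly above a
threshold (`min_frequency`, default 0.001). Frequency is computed over
the whole cohort, both arms combined; computing it per-arm would make
the candidate set depend on the treatment variable itself, and overall
frequency is the common choice in large-scale propensity work.

The propensity model is an L1-penalized logistic regression
(`glmnet`) of arm on the candidates, with the penalty chosen to
minimize 10-fold cross-validated binomial deviance over a seeded fold
assignment. We deliberately use the deviance-minimizing penalty rather
than the 1-SE rule: the non-zero coefficient set defines the
*matching covariates*, and the minimizing rule captures more of them.
"Non-zero" means exactly non-zero as stored — coordinate descent
produces exact zeros on the L1 path, so no epsilon threshold is needed.
Binary covariates enter as 0/1; continuous covariates are standardized
before penalization so the penalty treats all columns comparably, and
the stored scaling is replayed at prediction time.

One property worth knowing: the candidate sets are nested as the
frequency threshold rises, but the *matching-covariate count* from
refitted, re-tuned LASSOs is not guaranteed monotone between adjacent
thresholds — re-tuning the penalty on a smaller candidate set can
select more of it. Over a wide threshold gap the count does fall, and
the test suite asserts exactly that.

## Greedy propensity-score matching

Matching operates on the logit score, because the caliper is defined
there: caliper = `caliper_fraction` × pooled SD of logit scores, with
the unweighted two-group pooled SD `sqrt((s2_T + s2_C)/2)` computed on
pre-match scores. Units of the **smaller arm** are processed in a
seeded random permutation; each takes the nearest still-unmatched
opposite-arm unit within the caliper, ties broken by smallest subject
id (with a 1e-12 tolerance for floating-point equality of distances).
Greedy matching leaves the processing order unspecified in general; a
seeded random order avoids systematic order bias while staying
reproducible, and the smaller-arm perspective maximizes attainable
retention (every smaller-arm unit can in principle be matched).

## Cardinality matching as an integer program

With selection indicators `a_i`, `b_j` over the two arms, the program
maximizes `n = sum(a)` subject to `sum(a) = sum(b)` and, per matching
covariate `k` with positive pre-match pooled SD `s_pk`,

```
|sum_i a_i v_ik - sum_j b_j v_jk| <= criterion * s_pk * n
```

linearized as two inequalities (`n` is itself `sum(a)`, so the
constraint stays linear). `criterion = 0` collapses to equal matched
covariate sums — fine balance. For binary covariates with equal matched
group sizes, equal sums and exact marginal distributional balance
coincide, which is why the package implements fine balance as the
`delta = 0` special case of the SMD constraint. Covariates with zero
pre-match pooled SD carry no information and are excluded from the
constraints.

Three choices matter for scale and correctness:

- **Selection, not assignment.** The program selects subsets; it does
  not use pairwise assignment variables. The downstream analysis is
  unconditional, so only the selected sets matter, and selection keeps
  the variable count linear in subjects rather than quadratic.
- **Pattern aggregation.** Subjects with identical rows over the
  constrained covariates are interchangeable, so the program uses one
  bounded integer variable per distinct covariate pattern per arm. This
  is exact (any per-pattern count expands to concrete subjects — the
  lowest ids, deterministically) and typically shrinks a
  thousands-of-subjects instance to a few hundred variables.
- **Proven optimality by default.** The MILP backend (HiGHS, reached
  through the scientific Python runtime) runs at a relative gap of 0. A
  60-second default time limit guards against pathologically hard
  instances; hitting the limit without a usable incumbent is reported
  as an infeasible result, never silently relaxed. Fine balance over
  many covariates can genuinely fail to converge — the appropriate
  response is loosening the balance criterion, not trusting a
  heuristic answer.

Selected sets are rank-paired by propensity score (i-th ranked target
with i-th ranked comparator). Any pairing of the same sets yields the
same unconditional estimate — the test suite checks this invariance —
so rank pairing is merely a deterministic convention that keeps pair
files interpretable.

## Balance diagnostics

`SMD = (mean_T - mean_C) / s_p` with `s_p` the **pre-match** pooled SD
(unweighted two-group form, `n - 1` variances) even for post-match
tables, so matching is judged against the original scale of imbalance.
`|SMD| < 0.10` strictly counts as balanced; a covariate at exactly 0.10
is imbalanced. Covariates with zero pre-match pooled SD in a given
(sub)sample get an undefined SMD and are excluded from summaries rather
than counted as balanced — in small subsample draws many rare
covariates are simply unobserved. Per-draw reports pool by
concatenating SMDs across draws into one joint distribution; because
"average imbalance" across draws is ambiguous between counts and
proportions, the summary emits both.

## Time at risk and outcome models

Follow-up is intention-to-treat: day 1 post-index to the earliest of
the administrative study end, the end of continuous exposure under a
persistence window allowing at most 30 days between dispensings, and
the end of observation. Subjects with fewer than 1 day at risk are
excluded and counted. Cox models are *unconditional* (treatment-only),
treating matched pairs as an analytic cohort rather than stratifying by
pair; ties are handled with the Efron approximation because day-granular
times produce many ties. Fits with no events in an arm, or with a
monotone partial likelihood (detected by a diverging coefficient), are
flagged non-estimable and dropped from downstream fitting with their
count recorded.

Negative-control estimates within a subsample group are obtained by
fitting each outcome on the post-match observations stacked across all
draws of the group (a subject appearing in several draws contributes
once per draw). The pooled fit is unstratified by draw; a
draw-stratified alternative would be defensible but changes nothing
under the null and is not implemented.

## Empirical null, ESE and calibration

Negative-control log hazard ratios are modeled as
`theta_hat_i ~ N(beta_i, tau_i^2)` with `beta_i ~ N(mu, sigma^2)` —
`sigma` is interpreted as a standard deviation, so the marginal
likelihood is `N(mu, sigma^2 + tau_i^2)`. The MLE maximizes this over
`(mu, sigma >= 0)` via L-BFGS-B; a `sigma` estimate at the zero
boundary (systematic error present but homogeneous) is flagged with a
warning.

The expected systematic error is the folded-normal mean

```
ESE = sigma * sqrt(2/pi) * exp(-mu^2 / (2 sigma^2))
      + mu * (1 - 2 * pnorm(-mu / sigma))
```

reducing to `|mu|` at `sigma = 0`. Uncertainty comes from a random-walk
Metropolis-Hastings chain over `(mu, log sigma)` with flat priors on
that parameterization (no prior information is claimed; the flat prior
on `log sigma` keeps the chain off the boundary). The proposal SD
adapts toward a 20-50% acceptance rate during burn-in, in 50-iteration
windows, and is frozen afterwards so the post-burn-in chain is a valid
Markov chain. ESE is computed per retained sample; the credible
interval is the 2.5/97.5 percentile range. Defaults (10,000 iterations
after 1,000 burn-in) are generous for a 2-parameter posterior; the
suite cross-checks intervals against a dense posterior quadrature.

Calibration uses the null-based shift-and-inflate rule: calibrated
`p` is the two-sided tail probability of `theta_hat` under
`N(mu, sigma^2 + tau^2)`; the calibrated point estimate is
`theta_hat - mu` with standard error `sqrt(sigma^2 + tau^2)` and a
symmetric normal interval. Fuller calibration schemes also use
synthetic positive controls to let bias depend on effect size; with
negative controls only, the constant-bias rule is the version that is
identified, and it reduces to the uncalibrated statistics when the
fitted null is degenerate (`mu = 0`, `sigma = 0`).

## What the synthetic generator does and does not emulate

The generator (`sim_config()` / `generate_cohort()`) is first-class,
tested code. Its defaults are the study conditions used throughout the
tests:

- ~75/25 target/comparator split (`comparator_fraction = 0.25`), with
  the logistic-assignment intercept calibrated numerically so the
  marginal split holds regardless of confounding strength;
- sparse binary covariates with log-uniform prevalences
  (default range 0.002-0.3), emulating the long tail of rare codes that
  makes frequency-threshold feature selection meaningful; confounders
  are drawn from a common-prevalence range (0.05-0.3) so their
  confounding is expressed in finite samples;
- confounder effects on treatment alternate in sign with magnitudes
  0.3-1.0 on the log-odds scale; effects on outcome hazards default to
  half that, scaled per outcome by a uniform factor on (0.25, 1.75)
  (`outcome_effect_heterogeneity = 0.75`) — heterogeneity across
  outcomes is what gives the empirical null a positive `sigma`;
- age enters truth linearly but is exposed to models as 5-year band
  indicators, mirroring how demographics are coded in practice and
  keeping fine balance meaningful (an exact-sum constraint on a
  continuous covariate is neither realistic nor generally feasible);
- 105 negative controls by default, generated as exponential survival
  times whose rates depend on confounders but never on arm — the true
  hazard ratio is exactly 1 by construction; one safety outcome with
  true hazard ratio 3 in the target arm;
- dispensing-level exposure records (30-day supplies, geometric refill
  delays, geometric discontinuation), so the 30-day persistence rule in
  the time-at-risk builder operates on real gaps; a stored era end is
  verified in tests against recomputation from the raw dispensings;
- stratified subsample draws take `floor(fraction x arm size)` per arm
  without replacement — consistent with the 10%/1%/0.5% design — on
  independent seeded substreams.

What it does **not** emulate: code hierarchies and correlated covariate
clusters (covariates are independent given prevalence), calendar-time
trends, informative censoring, competing risks, or measurement error in
covariates. Passing tests therefore demonstrate correctness of the
algorithms under a known generating process, not robustness to every
feature of real claims data.

## Problem sizes and numerical tolerances

The test suite runs cohorts of 120-20,000 subjects. Exhaustive
enumeration validates the cardinality-matching optimum on 50 random
instances of up to 6 units per arm; fine-balance exactness is asserted
on a 2,000-subject cohort with LASSO-selected matching covariates
(solve time well under a minute); null recovery uses 20,000 subjects
and 50 negative controls. MCMC-versus-quadrature agreement is required
to 0.025 on ESE interval endpoints, reflecting Monte-Carlo error at
4,000-6,000 retained samples. Exact-zero assertions (fine-balance SMDs)
are genuinely exact: matched covariate sums are equal integers, so the
floating-point difference of means is identically zero.

## Known limitations

- Cardinality matching's solve time grows quickly with the number of
  fine-balance constraints; instances with many dozens of constrained
  covariates may hit the time limit (and are honestly reported as
  non-converged). Loosening the criterion or raising the
  candidate-frequency threshold is the practical remedy.
- The greedy matcher is quadratic in the worst case through tied runs,
  though sorted bidirectional search keeps typical instances near
  `O(n log n)`.
- Calibration assumes exchangeability of the safety outcome with the
  negative controls (same systematic-error distribution) and constant
  bias across effect sizes.
- The MILP backend requires the scientific Python runtime with SciPy;
  without it, cardinality matching raises an explicit error naming the
  missing capability (propensity matching and all diagnostics work
  regardless).
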