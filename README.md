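# lscmatch

Large-scale cardinality matching and propensity-score matching for
observational comparative cohort studies, with negative-control-based
quantification of residual confounding and empirical calibration of
effect estimates.

## The problem

Observational studies of two treatments (a *target* and an *active
comparator*, e.g. two first-line antihypertensive classes in a claims
database) must deal with confounded treatment assignment. The standard
remedy is 1:1 matching, classically on the propensity score. Greedy
propensity-score matching (PSM) degrades when covariate overlap is
limited — retention drops and matched groups stay imbalanced — which is
exactly the situation in small samples. Cardinality matching (CM) takes
the opposite route: it solves a mixed-integer program for the **largest**
1:1 matched sample that satisfies explicit covariate balance constraints.

`lscmatch` implements both at "large scale": the matching covariates are
selected empirically, as the covariates with non-zero coefficients in an
L1-penalized (LASSO) propensity model fitted over thousands of sparse
binary covariates, so both matchers adjust for the same
empirically-chosen set.

## The core pieces

**Cardinality matching.** With selection indicators $a_i$ (target arm)
and $b_j$ (comparator arm), the solver maximizes $n = \sum_i a_i$
subject to $\sum_i a_i = \sum_j b_j$ and, for every matching covariate
$k$,

$$\Big|\sum_i a_i v_{ik} - \sum_j b_j v_{jk}\Big| \le \delta_k \, n,
\qquad \delta_k = c \cdot s_{pk},$$

where $s_{pk}$ is the pre-match pooled standard deviation of covariate
$k$ and $c$ the balance criterion (0.01, 0.05, 0.10, or 0 for *fine
balance*, i.e. exact marginal distributional balance). Interchangeable
subjects are aggregated into covariate patterns, which keeps the integer
program small; solutions are proved optimal by the MILP backend.

**Propensity-score matching.** Greedy 1:1 nearest-neighbor matching on
the logit score within a caliper of 0.10 or 0.20 of the pooled standard
deviation of logit scores.

**Balance.** Standardized mean differences
$\mathrm{SMD} = (\bar{x}_{T} - \bar{x}_{C})/s_p$ with the *pre-match*
pooled SD in the denominator throughout; $|\mathrm{SMD}| < 0.10$ counts
as balanced; per-draw tables pool into joint distributions across
subsample draws.

**Residual confounding.** Negative-control outcomes (true hazard ratio
1) are analyzed with unconditional Cox models over intention-to-treat
time at risk (day 1 post-index to the earliest of study end, exposure
end under a 30-day persistence window, or observation end). Their log
hazard ratios $\hat\theta_i$ follow an empirical null
$\hat\theta_i \sim N(\mu + \theta_i, \sigma^2 + \tau_i^2)$ with
$\theta_i = 0$; the fitted $(\mu, \sigma)$ give the **expected
systematic error** $\mathrm{ESE} = E|\beta|$, $\beta \sim N(\mu,
\sigma^2)$, with 95% credible intervals from a random-walk
Metropolis-Hastings chain. Outcome estimates are calibrated against the
same null ($p$-value from $N(\mu, \sigma^2+\tau^2)$; shifted point
estimate with inflated standard error).

**Synthetic cohorts.** A seeded generator emulates a two-arm new-user
cohort: ~75/25 arm split, sparse high-dimensional binary covariates,
age bands, confounded logistic treatment assignment, dispensing-level
exposure records, and exponential survival outcomes whose
negative-control hazards never depend on the arm. Stratified subsample
draws (e.g. 10%/1%/0.5% with 5/50/100 draws) reproduce the
shrinking-sample evaluation design.

## Worked example

```r
library(lscmatch)

cohort <- generate_cohort(sim_config(
  n_subjects = 2000, n_binary_covariates = 20, n_confounders = 8,
  n_negative_controls = 10, seed = 202))

candidates    <- select_candidate_covariates(cohort, min_frequency = 0.02)
model         <- fit_propensity_model(cohort, candidates, seed = 303)
matching_covs <- extract_matching_covariates(model)
scores        <- predict_scores(model, cohort)

greedy_match(scores, cohort_arms(cohort), caliper_fraction = 0.10, seed = 1)
#> Match result (psm): 445 pairs
#>   settings: caliper_fraction=0.1; caliper=0.07631404; seed=1

cm <- cardinality_match(cohort, matching_covs, cm_config(0.01),
                        scores = scores)
cm
#> Match result (cm): 493 pairs
#>   settings: balance_criterion=0.01; solver_gap_tolerance=0
```

Cardinality matching keeps every comparator subject (493 pairs versus
445 under PSM) while meeting the 0.01 balance criterion:

```r
post <- balance_table(cohort, cm, matching_covs)
max(abs(post$smd[post$defined]))
#> [1] 0.0098      # pre-match maximum was 0.380
count_imbalanced(post)$count
#> [1] 0
```

Residual confounding, measured on the 10 negative controls before and
after matching, and the calibrated safety-outcome estimate:

```r
tar   <- build_time_at_risk(cohort)
tar_m <- tar[tar$subject_id %in% matched_ids(cm), ]
nc    <- sprintf("nc_%03d", 1:10)

ese_credible_interval(fit_outcome_models(tar, cohort$outcomes, nc),
                      iterations = 4000, burn_in = 1000, seed = 1)
#> ESE = 0.289 [95% CrI: (0.039, 0.487)]    # pre-match
ese_post <- ese_credible_interval(
  fit_outcome_models(tar_m, cohort$outcomes, nc),
  iterations = 4000, burn_in = 1000, seed = 1)
ese_post
#> ESE = 0.133 [95% CrI: (0.009, 0.418)]    # post-match

sf  <- fit_cox(tar_m, cohort$outcomes, "safety")
cal <- calibrate_estimate(ese_post$model, sf$log_hr, sf$se)
exp(c(sf$log_hr, cal$log_hr)); c(cal$uncalibrated$p, cal$p)
#> uncalibrated HR 4.89 (p = 5.2e-05); calibrated HR 4.28 (p = 2.1e-04)
```

The matched sample halves the expected systematic error, and calibration
widens the safety estimate's uncertainty to account for what remains.
(The generating safety hazard ratio here is 3; the matched estimate
still carries residual confounding from covariates the matching set does
not span.)

The full evaluation grid — sample groups x subsample draws x matching
methods, with pooled balance, ESE and calibrated estimates written as a
CSV/JSON bundle — runs through `run_evaluation()` /
`summarize_evaluation()`, or the CLI wrapper in `inst/cli/lscmatch.R`
(verbs `simulate`, `match`, `evaluate`, `summarize`).

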