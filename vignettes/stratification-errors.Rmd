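---
title: "Stratification errors in randomised trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratification errors in randomised trials: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mistrat)
```

## The problem

Stratified randomisation allocates participants to arms within subgroups
(strata) defined by a baseline covariate, using permuted blocks so the arms
stay balanced on that covariate. Adjusting the analysis for the
stratification variable is then required for valid inference: blocking
induces a positive correlation between the two arms' mean outcomes, and an
analysis that ignores it overstates its standard error, over-covers, and
loses power.

A *stratification error* occurs when the covariate is misclassified at
randomisation, so a participant is allocated within the wrong stratum.
Three candidate adjustment variables then exist: the randomisation strata
`Z` (wrong for some participants, but faithful to the design), the true
strata `X` (only available if every error is found), and the updated strata
`W` (errors discovered before analysis corrected, the rest left as
randomised). `mistrat` simulates this full process so the strategies can be
compared on equal footing.

## Data-generating process

Each simulated trial composes five steps, in the order they occur in a real
trial:

1. **True covariate.** `X_i ~ Bernoulli(pi)` i.i.d., default prevalence
   `pi = 0.5`.
2. **Misclassification.** Each `X_i` is flipped independently with a
   stratum-specific probability to give `Z_i`. Under the `equal` pattern
   both strata share the overall rate. Under `unequal_3x` one stratum's
   rate is three times the other's, with the overall (marginal) rate
   preserved: with `pi = 0.5` an overall rate `e` splits into `(e/2, 3e/2)`
   for strata 0 and 1. With `pi = 0.75` the higher rate goes to the more
   common stratum and the marginal rate is again preserved, giving
   `(0.08, 0.24)` at `e = 0.2`; the alternative reading (holding the lower
   stratum's rate fixed instead) would change the realised overall rate, so
   the marginal-preserving construction was chosen to mirror the
   `pi = 0.5` case. Flips precede allocation and are therefore independent
   of arm. A derived stratum rate above 1 makes the scenario infeasible and
   is rejected up front.
3. **Randomisation.** 1:1 permuted blocks of size 4 (configurable, any even
   size) within strata defined by `Z`. Participants are processed in
   enrollment (index) order; blocks are generated independently per stratum
   and the final block may be left incomplete, so the arm imbalance within
   a stratum never exceeds half the block size at any point of the
   sequence. Blocks are realised by ranking i.i.d. uniforms within each
   block, which yields a uniformly random permutation of the block's
   labels; generating blocks on demand is distributionally identical to
   pre-generating a fixed-length list.
4. **Discovery.** Each *error* is discovered independently with an
   arm-specific probability: equal in both arms (`equal`), always
   (`all`), or three times more likely in the intervention arm
   (`unequal_3x_intervention`, giving `(0.25, 0.75)` at an overall 50% rate
   under 1:1 allocation). `W_i` equals `X_i` where no error occurred or the
   error was discovered, and `Z_i` otherwise. Correct records are never
   "discovered": `W` can only move toward the truth.
5. **Outcomes.** `Y_i = alpha + beta_T T_i + beta_X X_i +
   beta_TX T_i X_i + e_i` with `e_i ~ N(0, 1)`. Outcomes depend on the
   *true* covariate only; `Z` and `W` affect the analysis, never the data.

The generator's defaults are the study conditions: `n = 1000`, `pi = 0.5`,
blocks of 4, unit residual SD, covariate effects of 1 or 3 residual SDs
(stratification should use strongly prognostic covariates, and differences
between methods vanish for weak ones), error rates of 1% (realistic) or 20%
(extreme, documented in the literature), and a 50% discovery rate when
discovery is partial. Sensitivity grids change one design element at a
time: `n = 200`, or `pi = 0.75`.

What the generator does *not* emulate: non-normal or heteroscedastic
outcomes, more than two strata or multiple stratification factors, unequal
allocation, minimisation or other covariate-adaptive schemes, and
structured (non-random) error or discovery mechanisms. Passing tests
therefore speak to the idealised linear-model setting, not to every real
trial.

## Estimation

All analyses are ordinary least squares with the classical model-based
variance `sigma2_hat * (D'D)^-1`, `sigma2_hat = RSS/(n - p)`. Inference
uses the t distribution with `n - p` degrees of freedom — the default of
standard regression software — so confidence intervals and the 5% test
agree by construction (`reject` is exactly "0 outside the 95% CI"). At
`n = 1000` this is numerically indistinguishable from normal-based
inference; at the `n = 200` sensitivity runs it matters slightly, and the
t-based convention is used throughout.

Strata enter as uncentred 0/1 indicators. In the interaction model
`Y ~ 1 + T + C + T:C` the treatment coefficient is therefore the subgroup
effect in stratum `C = 0` (true value `beta_T`) and the interaction
coefficient targets the subgroup difference (true value `beta_TX`). The
main-effects model's treatment coefficient targets the marginal effect
`beta_T + pi * beta_TX`; performance in scenarios generated with an
interaction is judged against that value, not `beta_T`. Jointly adjusting
for `Z` and `X` in one model is deliberately not offered: the two are
nearly collinear at low error rates.

Rank-deficient designs (e.g. a constant stratum indicator when the
prevalence is degenerate) raise an error naming the offending column;
`run_scenario()` drops such repetitions with a message and reports
`n_reps_used`, rather than silently imputing. Relative error in the model
SE is reported as `NA` with a warning when the empirical SE is zero.

## Performance measures and Monte Carlo SEs

For `R` repetitions with estimates `b_j`, model variances `v_j`, true value
`b`:

| measure | definition | MCSE |
|---|---|---|
| bias | `mean(b_j) - b` | `EmpSE / sqrt(R)` |
| EmpSE | `sqrt(sum((b_j - mean(b_j))^2) / (R - 1))` | `EmpSE / sqrt(2(R-1))` |
| ModSE | `sqrt(mean(v_j))` | `sqrt(var(v_j) / (4 R ModSE^2))` |
| relative % error | `100 (ModSE/EmpSE - 1)` | delta method on the ratio |
| coverage, rejection | % of repetitions | `100 sqrt(p(1-p)/R)` |

The delta-method MCSE for the relative error combines the ModSE and EmpSE
MCSEs as if independent; within a scenario they are positively correlated,
so this is slightly conservative. The arm-mean correlation is the Pearson
correlation of the per-repetition control and intervention sample means;
its sampling uncertainty is quoted on the Fisher-z scale as
`1/sqrt(R - 3)`. Analytic design checks (`power_two_sample_t()`,
`power_interaction()`) use exact noncentral-t power with both rejection
tails, so power equals the nominal level exactly at the null.

## Reproducibility and the seed policy

A master seed plus a scenario index defines an independent substream per
repetition (`rep_seed()`): repetition `j` of scenario `k` reseeds the
generator deterministically, so results are identical whether scenarios run
sequentially or in parallel, and any single repetition can be regenerated
in isolation. Within a repetition every analysis method sees the same
simulated dataset (common random numbers), which is what makes
within-scenario comparisons between methods tight. Scenario identifiers
are human-readable encodings of the parameter tuple rather than hashes, so
outputs remain joinable across runs *and* legible in result tables.

## Numerical choices

* OLS is solved by QR decomposition; the test suite checks equivalence to
  an explicit normal-equations solve to 1e-10 on random small designs.
* Exact-fit designs give zero residual variance, zero SEs and point
  intervals; the rejection rule (`CI excludes 0`) remains well defined.
* An empty randomisation stratum is skipped, not an error.
* Degenerate discovery rates behave as limits: rate 1 gives `W = X`,
  rate 0 gives `W = Z`.

## Problem sizes used by the tests

The shipped tests reproduce the study's headline results at reduced
repetition counts — 1,500–3,000 repetitions for the power/type-I-error
checks, 2,500 for the arm-mean correlations, and 300 per scenario for the
grid-wide unbiasedness and coverage sweep — with stochastic tolerances of
three Monte Carlo SEs at the repetition count actually run. The acceptance
script (`scripts/acceptance.R`) uses the full 10,000 repetitions per
scenario. A sense of the magnitudes involved:

```{r correlation, eval = FALSE}
# arm-mean correlation induced by blocking, no errors (about 0.11 / 0.53)
run_scenario(scenario_config(beta_x = 1), n_reps = 10000,
             seed = 1)$correlation$correlation
run_scenario(scenario_config(beta_x = 3), n_reps = 10000,
             seed = 1)$correlation$correlation
```

## Known limitations

Continuous, homoscedastic, normal outcomes only; a single binary
stratification factor; 1:1 allocation with classical (not
robust/sandwich) variances; treatment-by-covariate interaction limited to
the stratification variable itself. Real-data re-analyses are out of
scope: the package is a simulation laboratory, and its conclusions about
adjustment strategies transfer to real trials only to the extent the
linear-model assumptions do.
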