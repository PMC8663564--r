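---
title: "Quantifying learning and practice effects in high-frequency repeated testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying learning and practice effects in high-frequency repeated testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Smartphone-based functional tests — a symbol-digit substitution test for
processing speed, finger pinching and shape drawing for dexterity, walking,
turning and balance tests for mobility — let people with multiple sclerosis
test themselves at home, at high frequency, on their own schedule.
Repetition itself improves performance: users first learn how to execute a
test (a short-term effect over the first few trials) and then keep improving
slowly over tens of repetitions (a long-term practice effect). Both
inflate apparent improvement and mask deterioration, which matters wherever
there is no comparator arm: single-arm studies and intra-individual
monitoring. This package quantifies both effects on irregular, user-scheduled
series, and separates them from each other.

Analysis units are one participant's series for cognition and mobility tests
and one participant-hand's series for the dexterity tests (hands alternate in
the app). Each unit's records are indexed by repetition number; the model
time is either `repetition - 1` or weeks since the unit's first test.

## Pipeline

`run_analysis()` chains the stages; each is exported on its own.

1. **Selection** (`select_units`): keep units with at least 5 repetitions
   and at least 5 weeks between first and last test. We read "5 weeks" as
   at least 35 × 24 h of elapsed time, not calendar-week counting; the
   convention is recorded in the cohort provenance because borderline units
   move with it. `cohort_characteristics` summarizes repetition counts and
   intertest intervals as median (IQR; range), with linear-interpolation
   quantiles (R type 7) — quantile conventions shift these tables, so the
   choice is fixed and stated.
2. **Summary effects** (`score_triples`, `improvement_summary`): per-unit
   percent changes between the first, fifth and last scores, averaged with
   t-based 95% CIs. Percent changes are means of per-unit ratios (the pooled
   ratio-of-means is also reported); the fifth trial is the conventional
   boundary between short-term learning and long-term practice. Signs are
   never flipped: for the sway-path test (lower is better) improvements are
   negative. `fifth_to_last_regression` adjusts the fifth-to-last difference
   for age, first and fifth score, and the natural log of the repetition
   count (adherence is strongly right-skewed).
3. **Short-term learning** (`quantile_panel`): linear quantile regression of
   the first five trials at the 5th/25th/50th/75th/95th percentiles.
   Intercepts are anchored at trial 1, so they read as baseline performance
   for low, median and high performers; slopes are learning rates in metric
   units per repetition.
4. **Long-term practice gate**: a test is flagged when the 95% CI of the
   fifth-to-last mean improvement excludes zero AND the log-repetitions
   coefficient has p < .05. Only flagged tests get the learning-curve
   analysis — an unflagged (for example flat) cohort skips it.
5. **Learning curves** (`fit_linear_mixed`, `fit_quadratic_mixed`,
   `fit_spline`, `fit_bounded_growth`, `compare_models`,
   `practice_metrics`).

## The bounded growth model

The central model is exponential approach to an individual plateau,

$$y_{ij} = b_i + (a_i - b_i)\,e^{-c\,t_{ij}} + \varepsilon_{ij},$$

with baseline $a_i \sim N(\mu_{y_0}, \sigma^2_{y_0})$ and boundary
$b_i \sim N(\mu_b, \sigma^2_b)$ independent across and within units, a fixed
growth constant $c > 0$ shared by all units, and Gaussian residuals: 6 df in
total (3 fixed effects, 2 random-effect variances, 1 residual variance).
$t$ starts at 0, so $a_i$ is the expected first-trial score.

**Estimation.** For fixed $c$ the model is *linear* in both random effects:
with $w = e^{-ct}$, $y = a_i w + b_i (1 - w) + \varepsilon$. We exploit this
by profiling the exact marginal likelihood over $\log c$: each candidate $c$
is an exact ML linear-mixed fit in the basis $(w, 1-w)$ (via `lme4`), and
the outer one-dimensional profile is minimized by a bracketing grid around a
pooled-curve start followed by golden-section search. On short, unbalanced
series (median around 11 repetitions, range 5 to several hundred) we found
iterated-linearization schemes to carry an upward finite-sample bias of
about 10% in $c$; the profiled exact likelihood removes it (the package's
parameter-recovery tests document this at 200 units). Starting values: mean
first score for $\mu_{y_0}$, mean of per-unit last-quartile means for
$\mu_b$, and a 50-point log-grid profile of $c$ with closed-form linear
sub-fits. The Wald CI for $c$ uses the curvature of the profile deviance;
CIs for $\mu_{y_0}$ and $\mu_b$ come from the sub-fit at the optimum.

With `random = FALSE` both variances are constrained to zero and the fit
reduces to pooled nonlinear least squares (Levenberg–Marquardt), which the
test suite checks against an independent grid-search oracle to 1e-6.

**Degenerate inputs.** A growth constant collapsing toward 0 (flat series:
the boundary is unidentifiable) or diverging (instantaneous learning: the
baseline is unidentifiable) raises an informative error advising the linear
model rather than returning a meaningless fit.

**Derived metrics** (`practice_metrics`): the practice point
$t_p = -\ln(1-p)/c$ is when a fraction $p$ of the baseline-to-boundary gap
is closed; for any $c$, $t_{90}/t_{50} = \ln 10 / \ln 2 \approx 3.32$, so
rounded practice points (for reporting) are emitted alongside raw ones. The
boundary improvement over baseline is reported two ways: the mean of
per-unit BLUP ratios $100\,(b_i - a_i)/a_i$ with a t-based CI (subject-level
averaging, the tighter interval), and the fixed-effect ratio
$100\,(\mu_b - \mu_{y_0})/\mu_{y_0}$ with a delta-method CI. The tangent
slope $m(t) = c\,(\mu_b - \mu_{y_0})\,e^{-ct}$ annotates the curve.

## The three comparison models

- linear mixed, $y = \beta_0 + \beta_1 t + u_i + \varepsilon$ (df = 4), and
  quadratic mixed with an added fixed $t^2$ (df = 5), both ML via `lme4`;
- a penalized cubic regression spline of $y$ on $t$ (basis dimension 10,
  smoothing parameter by GCV, `mgcv`), whose effective df is the trace of
  the influence matrix. By default the GAM carries a unit-level
  random-intercept smooth so that its residuals are conditional like the
  mixed models' (`unit_intercept = FALSE` gives a pure population smoother);
  without the grouping term, the spline's RMSE absorbs the entire
  between-unit variance and cannot be compared on the same footing.

All models are compared on **conditional RMSE** — root mean squared residual
with unit-level (BLUP-inclusive) predictions — and their (effective) df.
Conditional rather than marginal residuals is a stated convention: it makes
the four models comparable on fit-to-observations. On bounded-growth data
the expected ordering is bounded < spline ≤ quadratic < linear.

## The synthetic cohort generator

`simulate_cohort(sim_config(...), seed)` generates cohorts that emulate the
public observational data the pipeline targets, with known ground truth per
unit (`truth`: baseline, boundary, repetition count, age):

- per-unit bounded-growth trajectories on the repetition axis with
  independent Gaussian baseline and boundary and additive Gaussian noise;
- right-skewed repetition counts: lognormal rounded up, with `meanlog` and
  `sdlog` solved in closed form from target median and IQR
  ($\sigma = \operatorname{asinh}(\mathrm{IQR}/2m)/z_{0.75}$), hard-capped
  at a maximum (defaults 11 / 11 / 119, the cognition-arm profile);
- intertest intervals lognormal in days, floored at the app-enforced
  per-test minimum (7 d for the symbol-digit test, 2 d per hand for
  dexterity, 1 d for mobility); dexterity tests emit two interleaved
  hand-units per participant, the right hand offset by one day;
- age Normal(50, 11) tied to the repetition count by a Gaussian copula at
  r = 0.2 — a knob, not a behavioral mechanism;
- one child random stream per participant derived from the root seed, so
  growing `n_units` extends a cohort without reshuffling existing units and
  identical (config, seed) is bit-reproducible.

Defaults are the cognition-arm study conditions: 262 units, baseline mean
41.0, boundary mean 57.7, $c = \ln 2 / 11$ per repetition (half the practice
effect after 11 repetitions), residual SD 3.3. The between-unit SDs (10) are
not printed in the source material; they were chosen once to reproduce the
reported spread of baseline percentiles (roughly 22 to 55 correct responses
across the 5th–95th percentiles) and are not tuned thereafter.

What the generator does *not* emulate: relapses or disease progression,
sensor-level noise physics, missing-not-at-random dropout, or any dependence
of adherence on performance. Passing recovery tests therefore show that the
estimators are correct under the stated generating process, not that real
cohorts satisfy that process.

## Quantile regression internals

No quantile-regression dependency is assumed: the two-parameter pinball-loss
minimization is implemented in compiled code. For small samples (n ≤ 250)
the optimum is found by exact enumeration of all lines through point pairs
with distinct trial numbers — an LP vertex argument guarantees such an
interpolating optimum exists — with ties broken toward the lexicographically
smallest (intercept, slope) for determinism. Larger samples use
golden-section search on the convex piecewise-linear profile of the loss in
the slope (the optimal intercept for a fixed slope is a quantile of the
partial residuals), then snap to the best interpolating line through
near-active points when that does not increase the loss.

Inference is by **cluster bootstrap**: units, not rows, are resampled
(repeated measures violate row independence), default 1000 replicates;
standard errors, normal-approximation CIs and p-values, and the joint
covariance of the five slopes come from the replicates. Slope p-values are
Bonferroni-adjusted over the family of five slopes per test; intercepts are
reported with unadjusted CIs, since learning-rate inference is the stated
target. Equality of the five learning rates is tested with a Wald statistic
on the four successive-difference contrasts,
$W = (D\hat\beta)^\top (D \hat V D^\top)^{-1} (D\hat\beta) \sim \chi^2_4$
— an ANOVA-type test that is invariant to reordering the percentiles. When
the estimated slopes are exactly equal, $W = 0$ is returned without
inverting the (then singular) covariance.

## Numerical and design choices

- Timestamp parsing is ISO-8601; date-only stamps are imputed at 12:00 so
  day-resolution data cannot flip across midnight in week arithmetic.
  Same-timestamp records keep stable input order (multiple same-day
  repetitions are possible for the mobility tests; ordering them by input
  row is our convention — the source material does not state one).
- The fifth-to-last CI is t-based (bootstrap would be the alternative; the
  source does not say which was used).
- `correct_sdmt` divides symbol-digit scores by the 15-second digit-tapping
  "baseline" count to remove the motor component; records with missing or
  zero baseline are dropped and counted, and the transform refuses to run
  twice (corrected scores are no longer integer counts).
- The long-term practice gate operationalizes "significant mean difference
  plus positive adherence association" as: 5th-to-last CI excludes 0 AND
  log-repetitions p < .05.
- End-to-end determinism: identical configuration and seed give
  byte-identical JSON/TSV report bundles.

## Problem sizes used in the tests

Parameter recovery runs 10 seeds of 200 units at the cognition-arm
conditions (recovery within 5% for the means, 10% for $c$, in at least 9 of
10); model-ordering checks use 10 seeds of 150 units; the slope-equality
size calibration runs 200 simulations of 200 units with 200 bootstrap
replicates each (the package default stays at 1000 replicates — the
calibration uses fewer because it repeats the whole panel 200 times);
quantile fits are verified against exhaustive pairwise enumeration on
instances of up to 12 points. These sizes are the package's choices for a
desk-scale, fully reproducible suite.

## Known limitations

- The bounded growth model assumes data missing at random given the unit;
  adherence correlated with unobserved severity would bias boundary
  estimates, and the generator provides no such mechanism to test against.
- The spline comparison depends on the grouping convention (see above);
  with `unit_intercept = FALSE` its RMSE is not comparable to the mixed
  models' conditional RMSE.
- Quantile-crossing is reported (intercepts should be nondecreasing in the
  percentile) but not repaired.
- Percent-change summaries exclude units whose first or fifth score is zero
  (flagged, counted); metrics with frequent zeros need a different summary.

## A worked run

```{r example}
library(practicecurve)

cfg <- sim_config()            # cognition-arm study conditions
sim <- simulate_cohort(cfg, seed = 1)
res <- run_analysis(sim$cohort, n_boot = 500, seed = 1)
print(res)

sens <- run_sensitivity(sim$cohort, n_boot = 500, seed = 1)
print(sens)
```
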