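---
title: "Methods: case-crossover DLNM for warm-season temperature and acute mental-health encounters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-crossover DLNM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdlnm)
```

## The design and the model

The package estimates short-term associations between daily minimum
temperature (Tmin, a proxy for nighttime heat and sleep disruption) and
acute mental-health encounters in a time-stratified case-crossover design.
Each encounter contributes one matched set: its admission day (case day) and
every other day of the same weekday within the same calendar month and year
(3 or 4 referent days, depending on how often that weekday occurs in the
month). Because case and referent days belong to the same person-month-weekday
cell, all time-invariant personal characteristics, secular trends,
seasonality and day-of-week patterns cancel out of the comparison; only
exposures varying within the month remain.

Temperature enters through a distributed lag non-linear model. For each day
the exposure history over lags 0–5 is expanded into a cross-basis: a natural
cubic spline basis $b(t)$ in Tmin (default 3 df) copied once per integer lag
day, giving $3 \times 6 = 18$ unconstrained columns ("integer lag
functions": one coefficient vector per lag, no smoothing across lags). The
coefficients are estimated by conditional logistic regression,

$$\ell(\beta) = \sum_i \Big[ x_{\text{case},i}'\beta -
  \log \sum_{j \in \text{set } i} \exp(x_j'\beta) \Big],$$

maximized directly (this is exact for 1:m matched sets). The cumulative log
odds ratio comparing temperature $t$ to a reference $r$ sums the same spline
contrast over all lag blocks,
$\log OR(t\,\text{vs}\,r) = \sum_{l=0}^{5} [b(t) - b(r)]'\beta_l$, with
variance $c'\Sigma c$ from the inverse observed information. The reference is
the minimum-risk temperature (MRT): the temperature at which the fitted
cumulative curve is lowest over the observed warm-season range. Odds ratios
are reported at the 95th percentile of the June–August Tmin distribution with
Wald intervals on the log scale.

Encounters sharing a case day within an analysis subset have identical
matched sets, so the pipeline collapses them into one stratum with a count
weight; the conditional likelihood is unchanged. Strata whose rows are all
identical (e.g. under constant exposure) contribute a constant to the
likelihood; they are counted and retained but carry no information.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| Spline df | 3 | 1 + number of interior knots; 5 df available via `run_config(spline_df = 5)` |
| Interior knots | sample tertiles | equally spaced quantiles of the analysis-sample Tmin (case and referent days), the DLNM-literature convention; recorded in the manifest because results depend on them |
| Boundary knots | observed min/max | of the analysis sample |
| Lags | 0–5 days | integer lag basis |
| Elevated temperature | 95th percentile | type-7 (linear order-statistic interpolation) quantile of warm-season Tmin |
| MRT search | observed range, 0.1 °F grid | ties broken toward the lowest temperature |
| Minimum subgroup size | 500 encounters | smaller subgroups are reported as skipped |
| Subgroup reference | own MRT | subgroups re-estimate their MRT (the minimum-risk point genuinely differs across subgroups); `subgroup_reference = "shared"` reuses the age group's MRT |
| Confidence level | 0.95 | normal-theory intervals on the log-OR scale |

All temperatures are degrees Fahrenheit throughout; the single °F→°C
conversion lives in the humidity formula. Relative humidity uses the
Magnus saturation-vapour-pressure approximation with coefficients
17.625/243.04 — the documented convention of the standard weather-conversion
toolchain — clamped to (0, 100]; supersaturated inputs (dew point above mean
temperature) are rejected rather than silently truncated.

## Numerical choices

- **Spline construction.** The natural cubic spline basis uses the
  truncated-power construction with natural constraints (linear beyond the
  boundary knots, $C^2$ everywhere). Any construction spanning the same
  space gives identical fits; the test suite verifies span-invariance against
  an invertible column transform and against a B-spline-based construction.
- **Fitting.** Newton–Raphson from $\beta = 0$ with analytic gradient and
  Hessian, step-halving on likelihood decrease, convergence at max
  $|$score$| < 10^{-8}$ or relative log-likelihood change $< 10^{-12}$, at
  most 50 iterations. No regularization: rank-deficiency on the informative
  strata and separation (a column whose case value is a within-stratum
  extreme everywhere) are explicit, named errors.
- **Per-stratum stabilization.** The log-sum-exp in the likelihood subtracts
  the stratum maximum before exponentiation.
- **Quantiles.** All percentiles use R's type-7 rule (linear interpolation
  between order statistics); the rule is recorded in output metadata.
- **Degenerate inputs.** Days with no reporting station are exposure gaps;
  any matched set whose lag window touches a gap is dropped whole (keeping
  referent sets balanced within month) and counted in the attrition log. A
  lag window extending before the series start is a coverage error naming
  the earliest unservable date — June case days need exposure back to
  May 27.

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: seven warm seasons
(2005–2011) of daily Tmin built from a seasonal sinusoid plus AR(1) noise,
calibrated analytically so the June–August marginal mean and SD are 67.9 and
5.4 °F; four synthetic stations whose daily deviations average to zero, so
station averaging reproduces the citywide series exactly; and Poisson daily
encounter counts per age group (≈7.8/day total, ≈5,000 encounters per
simulated study) whose log-rate carries day-of-week, month and year effects
plus a known temperature term $\sum_l w_l f(\text{Tmin}_{d-l})$. The default
true response is U-shaped, $f(t) = 0.004\,(t - 69)^2$, with decaying lag
weights $(0.30, 0.25, 0.20, 0.15, 0.07, 0.03)$ summing to 1 — a cumulative
log OR of about 0.20 (OR ≈ 1.22) at 76 °F versus the 69 °F vertex,
qualitatively matching the U-shaped children's exposure-response with an MRT
near 69 °F and an elevated-temperature OR near 1.3 reported in this
literature. Calendar confounding is on by default, so recovery tests
demonstrate that the matched design removes it rather than assuming it away.
Poisson event generation (rather than per-person Bernoulli) is used because
matched sets built from visit days yield the identical conditional
likelihood either way.

The generator does **not** emulate: spatial exposure heterogeneity across a
real station network, within-person repeat-visit correlation, seasonality in
the diagnosis mix, coding noise in claims data, or exposure measurement
error. Passing tests therefore show that the estimator recovers the estimand
under the design's own assumptions — not that those assumptions hold in any
particular claims database.

## What the test suite checks

Scales were chosen to exercise the statistical properties at desk scale: 100
null studies (temperature weights zero, confounding on) gate the rate of 95%
CIs excluding OR = 1; 50 studies with the default U-shaped truth gate mean
bias of the cumulative log OR at the 95th percentile, CI coverage, and MRT
error; 50 paired studies compare strong-confounding versus no-confounding
generators; 20 paired studies compare humidity-adjusted and unadjusted fits
when humidity is generated independently of the outcome; and 200 draws
calibrate Cochran's Q under a common true effect. Single-study Monte-Carlo
checks use a pooled 6–25 age group so each study contributes one fit at the
full ≈5,000-encounter size.

## Known limitations

- **MRT selection.** The reference is the argmin of a noisily estimated
  curve. Under a null effect this selection pushes the OR at the 95th
  percentile away from 1, so CI exclusion rates run somewhat above the
  nominal 5%; the same mechanism adds a small upward bias to estimated
  contrasts under non-null effects. This mirrors the field's standard
  practice of MRT-referenced ORs; uncertainty in the MRT itself is *not*
  propagated into the CI (the conventional choice, documented as a caveat).
- **Model-class approximation.** A 3-df natural spline cannot represent a
  globally quadratic response exactly (its tails are constrained linear), so
  even at large n the cumulative contrast at the 95th percentile carries a
  small approximation offset relative to the generating quadratic. This is a
  property of the estimand the spline model targets, shared with any DLNM
  analysis at fixed df, not a fitting defect.
- **Taxonomy.** The shipped subcategory map is an approximate, prefix-based
  rendering of the usual paediatric mental-health groupings; exact code
  lists vary across studies and should be supplied via
  `read_taxonomy_yaml()` for any substantive use. Categories whose
  conventional ICD-9 roots lie outside the default 290–299 primary-diagnosis
  range only become active if `mh_root_range` is widened.
- **Scope.** Visit-level records are analyzed as-is (no de-duplication of
  repeat visits, as in claims-based practice); variances are model-based
  (no robust/sandwich correction); referent schemes other than
  time-stratified, penalized splines, and non-integer lag bases are out of
  scope.
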