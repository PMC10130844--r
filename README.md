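# ccdlnm

Case-crossover distributed-lag non-linear models for short-term heat effects
on acute healthcare encounters.

`ccdlnm` is for environmental epidemiologists studying how daily ambient
temperature affects same-week risk of acute events — here, mental-health
related emergency-department visits and hospitalizations in young people
during the warm season (June–August). It implements the full analysis chain:

- **Exposure construction**: citywide daily minimum temperature (Tmin, °F) as
  the unweighted mean of weather-station records, with relative humidity
  derived from mean and dew-point temperature via the Magnus formula.
- **Cohort and outcomes**: ICD-9 based case definition (primary diagnosis
  290–299), configurable mental-health subcategories, a separate
  suicide/self-harm flag from E95x external-cause codes, and fixed-order
  cohort filters (season/year, age 6–25, unscheduled, diagnosis) with an
  attrition log.
- **Design**: time-stratified case-crossover — each encounter's case day is
  matched to all other days of the same weekday, month and year (3 or 4
  referents), eliminating time-invariant confounders and calendar effects by
  design.
- **Model**: a distributed lag non-linear model (DLNM). Tmin enters through a
  natural cubic spline basis `b(t)` (default 3 df, interior knots at sample
  tertiles, boundary knots at the observed range) replicated over integer
  lags 0–5 (one coefficient block per lag). The cross-basis coefficients are
  estimated by conditional logistic regression on the matched sets, maximizing

  `L(β) = Σ_i [ x'_case,i β − log Σ_{j ∈ set i} exp(x'_j β) ]`

  with an analytic Newton–Raphson fitter written for exact 1:m matching.
- **Effects**: the cumulative exposure-response over lags 0–5,
  `log OR(t vs r) = Σ_l [b(t) − b(r)]' β_l`, referenced at the minimum-risk
  temperature (MRT, the curve's argmin over the observed range), cumulative
  ORs with Wald 95% CIs at the warm-season 95th-percentile temperature,
  subgroup estimates (skipping subgroups under 500 encounters), and Cochran's
  Q homogeneity tests across subgroup levels.
- **Synthetic data**: a generator that emulates the study's structure — seven
  warm seasons of AR(1)-plus-sinusoid Tmin (June–August mean 67.9 °F, SD
  5.4 °F), Poisson encounter counts with day-of-week/month/year confounding
  and a known U-shaped lag-distributed temperature effect — so the entire
  pipeline is testable without any restricted claims data.

## Worked example

```r
library(ccdlnm)

cfg   <- sim_config(seed = 1)           # the default study conditions
study <- simulate_study(cfg)            # exposure series + encounter line list
run   <- run_analysis(study$exposure, study$encounters, run_config())
print(run)
```

```
Case-crossover DLNM run (main), elevated T = 76.5F
 age_group    n    mrt_f       or    ci_low  ci_high status
     12-17 1937 69.42684 1.212959 0.9386220 1.567477     ok
     18-25 2873 70.22684 1.429821 1.1604950 1.761651     ok
      6-11  873 65.92684 1.366334 0.9176161 2.034478     ok
```

Each row is one age group: `n` encounters entered the matched design, `mrt_f`
is the estimated minimum-risk temperature (°F), and `or` with (`ci_low`,
`ci_high`) is the cumulative odds ratio over lags 0–5 comparing the
warm-season 95th-percentile Tmin (76.5 °F here) against the MRT. The
generator's true cumulative log OR at 76.5 °F vs its 69 °F vertex is 0.22
(OR 1.25), so all three estimates bracket the truth. `run$results` adds the
subgroup rows (sex, race/ethnicity, payer, diagnosis subcategory,
suicide/self-harm), `run$heterogeneity` the Cochran's Q tests, e.g. for young
adults:

```
 variant age_group    variable k        Q df         p
    main     18-25         sex 2 2.332405  1 0.1267060
    main     18-25    race_eth 4 1.284780  3 0.7327503
    main     18-25       payer 4 2.437234  3 0.4867412
    main     18-25 subcategory 3 4.168178  2 0.1244204
```

Sensitivity variants re-use the same machinery:

```r
run_rh <- run_sensitivity(study$exposure, study$encounters, rh_adjust = TRUE)
run_ja <- run_sensitivity(study$exposure, study$encounters, months_restrict = 7:8)
```

A thin command-line wrapper with `simulate`, `run`, `sensitivity` and
`report` subcommands is installed at `inst/cli/ccdlnm.R`.

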