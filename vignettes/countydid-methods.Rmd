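---
title: "Methods: difference-in-differences for county-year rate panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: difference-in-differences for county-year rate panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countydid)
```

## The problem

`countydid` evaluates the effect of staggered county-level policy adoption —
the motivating case is federal funding for comprehensive sex education — on a
demographic rate outcome, the teen birth rate R (births per 1,000 women aged
14–19, from single-year-of-age birth and population counts). Because the
real natality microdata behind such analyses are restricted, the package
pairs the estimators with a synthetic county-panel generator whose ground
truth is known, so every estimator can be validated by simulation rather
than by re-running the original confidential analysis.

The outcome is `log(1 + R)`. The log keeps coefficients readable as
approximate percent changes in the rate; adding 1 keeps county-years with
zero births finite. `interpret_as_percent()` reports both the exact
`100(exp(b) − 1)` and the conventional rough `100 b` readings.

Treatment is a binary county-level funding indicator, lagged one year in the
analysis rows: a conception affected by programming in year g is carried to
term in year g + 1, so a county first funded in g first contributes a
treated observation in year g + 1. The lag is applied once, in
`build_analysis_rows()`; both estimator families then treat the lagged
indicator as "the" treatment, and the group index g used by the group-time
estimator is the first *treated analysis year* (funding year + 1).

## Estimators

### Two-way fixed-effects models (Models 1–3)

`fit_twfe()` estimates

* Model 1: `log(1+R) ~ treat + county FE + state-year FE`
* Model 2: adds the lagged time-varying covariates (distance to the nearest
  abortion provider; unemployment, median household income, poverty; percent
  of teen women aged 16–19; percent White, Black, Hispanic)
* Model 3: adds county-specific linear time trends

The state-year fixed effect is one intercept per (state, year) cell — not
separate state and year effects — so any statewide annual shock (e.g. a
state education mandate) is absorbed. Fixed effects are absorbed by
alternating-projection demeaning (tolerance 1e-10 on the maximum change per
sweep), which scales to thousands of counties; the dummy-variable OLS fit is
retained in the test suite as the oracle on small instances, and the two
agree to 1e-8. County trends are absorbed jointly with the county intercepts
by an exact within-county projection on `[1, t − t̄]`.

Collinear columns are dropped deterministically by QR with column pivoting
after rescaling each demeaned column by its pre-demeaning norm; columns
fully absorbed by the fixed effects (e.g. a covariate constant within
county) are detected relative to their own scale and reported in
`$dropped`. Singleton fixed-effect groups are retained, matching the
dummy-OLS oracle.

Standard errors cluster at the county level with the CR1 correction
`G/(G−1) · (N−1)/(N−K)`, and confidence intervals use t critical values with
G − 1 degrees of freedom. K counts the absorbed parameters through the
balanced-panel nesting identity (counties + state-year cells − states, plus
counties − states when trends are included); `build_analysis_rows()`
enforces the balance this relies on. With every observation its own cluster
and the correction off, the estimator reduces to HC0 — a degenerate identity
the tests exercise, alongside an independent cross-check against
`sandwich::vcovCL`.

### Group-time ATT for staggered adoption

Static two-way fixed-effects coefficients under staggered adoption are
weighted averages with potentially negative weights, so `att_gt()`
implements group-time average treatment effects ATT(g, t): the average
effect in calendar year t for the cohort first treated in year g, compared
against **never-treated** counties only (the design contrasts funded
counties with never-funded ones; not-yet-treated comparisons are
deliberately out of scope). Post-treatment cells (t ≥ g) difference
outcomes against the fixed base period g − 1; pre-treatment cells use the
varying base t − 1, i.e. year-on-year pseudo-ATTs that serve as
parallel-trend diagnostics.

The unconditional estimator is the difference of mean outcome changes. The
conditional estimator is doubly robust: an outcome regression of the
never-treated change on the Model-2 covariates measured at the cell's base
period, combined with inverse-probability weights from a logistic
group-membership score, consistent if either nuisance model is correct
(pure regression-adjustment and pure IPW variants are selectable). The
influence function includes the estimation effect of both nuisance fits:
writing θ_T and θ_C for the normalized treated and reweighted-comparison
means of `ΔY − m(X)`, the per-county contribution is

```
ψ = w_T(ΔY − m − θ_T) − w_C(ΔY − m − θ_C)
    − IF(β)'(E[w_T X] − E[w_C X])        (outcome-regression effect)
    − IF(γ)' E[w_C X (ΔY − m − θ_C)]     (propensity effect)
```

with IF(β) and IF(γ) the OLS and logit score influence functions. With a
degenerate (constant) covariate all correction terms vanish and the
conditional estimator equals the unconditional one exactly, including its
standard error — an identity in the test suite. Estimated propensities
within 1e-6 of 1 raise an overlap error naming the offending counties.

Aggregations follow the group-time design: the **overall ATT** averages each
cohort's time-averaged post-treatment effects with weights proportional to
treated-cohort size (cell-count weighting is available as an option — the
choice between them is genuinely open, and group-size weighting is the
default); the **event study** re-indexes cells by event time e = t − g and
averages cohorts observing each e. Both propagate the influence functions,
including the estimation effect of the cohort-share weights, so standard
errors come from a single per-county influence vector.

### Multiplier bootstrap and uniform bands

`multiplier_bootstrap()` perturbs the per-county influence contributions
with Rademacher weights (999 replications by default, seeded). Pointwise
scales use the bootstrap interquartile range divided by the normal IQR —
robust to heavy-tailed draws — and the simultaneous critical value is the
95% bootstrap quantile of the maximum absolute studentized deviation across
event times, giving uniform (sup-t) bands that contain the pointwise ones.

### Pre-trend Wald test

`pretrend_wald()` computes `a' V⁻¹ a` against a chi-square with df equal to
the number of pre-period estimates (a singular covariance falls back to a
pseudo-inverse with reduced df and a warning). By default `fit_csdid()`
feeds it the event-study pre-period estimates within five years of
adoption. Two considerations fix that window: the full pre-period vector of
a 22-year panel has ~20 entries whose joint covariance must be estimated
from a few dozen treated counties, which makes the chi-square reference
distribution anti-conservative; and differential trends close to adoption
are the ones that threaten identification. Because consecutive year-on-year
pre-ATTs share outcome levels and are negatively correlated, the windowed
test still telescopes into a powerful test against sustained linear
differential trends. The full window is available via `pre_window = Inf`.

## The synthetic panel generator

`generate_panel(sim_config())` draws a balanced county-year panel from the
model the estimators assume:

```
log(1 + R_it) = log(1 + R0) + δ(t − t0) + α_i + φ_s(i),t + β_i(t − t0)
                + x_{i,t−1}'κ + τ(t − g_i − 1)·1{t ≥ g_i + 1} + ε_it
```

with county intercepts α, state-year shocks φ, a common secular decline δ,
optional county trend slopes β, covariate effects κ on last year's
covariates, and the event-time effect path τ(·) switching on one year after
the funding year. Defaults reproduce the study conditions of the motivating
analysis: years 1996–2017; 2,927 counties in 49 states (48 × 60 + 47, since
2,927 is prime); staggered cohorts of 36 counties funded from 2010 and 19
more from 2015 (55 total, matching the published funding-status table); and
a default τ ramping from −0.015 at event time 0 to −0.07 at event time 4,
flat thereafter — the published event-study shape.

Parameter defaults and why:

* `base_rate = 40` births per 1,000 and `secular_trend = −0.02`/year put the
  level and the national decline of the outcome on the scale of US teen
  birth rates over 1996–2017.
* `sigma_county = 0.35`, `sigma_stateyear = 0.04`, `sigma_trend = 0.008`
  give persistent cross-county heterogeneity, statewide annual shocks and
  slow heterogeneous drifts of a few percent per year.
* `sigma_noise = 0.08` was calibrated so that simulated event-study standard
  errors at the default cohort sizes (~1.5–2%) match the uncertainty
  reported for the real county panel's first-year event-study estimate.
* Covariates are AR(1) processes around state-level means — the source
  analysis gives no covariate-generating process, and any smooth persistent
  process exercises the lag/adjustment machinery. The outcome loads on the
  *previous* year's covariates, so models with one-year-lagged covariates
  are correctly specified.
* The abortion-distance covariate is observed only in 2000, 2011 and 2014
  (elsewhere blank, to be filled by `apply_sample_filters()`'s linear
  interpolation/extrapolation — mirroring how the sparse real measure is
  handled). Within county it is exactly piecewise linear with a slope change
  at the middle knot, so interpolation reconstructs it without error; a
  globally linear series was rejected because it would be perfectly
  collinear with Model 3's county trends.
* Ages 14–19 populations are drawn once per county (log-normal county size ×
  age profile) and perturbed by small annual multiplicative noise —
  realistic denominators without demographic dynamics.
* `trend_adoption_shift` adds a mean shift to treated counties' trend
  slopes, creating the adoption–trend confounding under which the static
  Model 1 coefficient is biased while Model 3 and the group-time estimator
  are not (or much less so).

Two outcome modes: `gaussian_rate` (default) generates `log(1 + R)` from
the linear model exactly and stores real-valued expected births, so that
model-based recovery is exact — on noiseless draws Model 3 and the
group-time estimator return a constant effect to 1e-8; `poisson_births`
draws integer births per age as Poisson counts with mean `pop · R / 1000`,
adding the count-level noise of real vital-statistics data.

`SimTruth` records two true overall ATTs, because the estimators target
different weightings of the same effect path: the treated-cell-weighted mean
(every treated county-year counts equally) and the group-size-weighted mean
of cohort time-averages (the estimand of the overall group-time
aggregation). Recovery tests compare each estimator to its matching
estimand.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: no geographic structure beyond state nesting, no
migration or evolving age composition, no serial correlation in the
idiosyncratic error beyond the county trend, no treatment-effect
heterogeneity across counties within a cohort, and no feedback from
outcomes to adoption.

## Sample construction

`apply_sample_filters()` applies the exclusion rules of the motivating
design in a fixed order, attributing a county failing several rules to the
first (the source lists the rules but not an attribution; ordered
attribution makes the report deterministic): (1) any year of zero female
teen population, or a flagged reporting-area change (the flag is an input —
it has no operational definition to compute from); (2) prior
abstinence-only funding (an input list; re-including those counties is a
robustness exercise, not reproduced here); (3) a missing year in any
time-varying covariate, *after* sparse covariates are filled by
interpolation, which is how the sparse distance measure is meant to be
used; (4) funded outside the two main award cohorts; (5) excluded states
(the Hawaii analog). The filters are idempotent.

`build_analysis_rows()` defaults to the pooled 14–19 rate
(`age_mode = "aggregate"`): the headline published estimate is reported for
teens 14–19 as a single quantity, although the estimating equations are
written age-specifically. Both readings are implemented —
`age_specific` stacks single-year-of-age rows under the same
specification — and neither is asserted to be the source's exact choice.
Rows are unweighted by default, with population weighting available through
the `weight` column and `fit_twfe(weights = )`.

## Numerical choices

* Demeaning tolerance 1e-10 (relative to the data scale), with a hard sweep
  cap and warning.
* Rank decisions on demeaned designs are made after rescaling columns by
  their pre-demeaning norms, so a covariate absorbed by the fixed effects is
  dropped regardless of its units; dropped columns are reported.
* The logistic propensity fit is run on the (collinearity-reduced)
  covariates with an intercept; overlap failures error rather than truncate.
* Zero influence contributions give degenerate (zero-width) bootstrap
  bands rather than errors.
* Anticipation is fixed at zero beyond the built-in one-year lag.
* All randomness is seeded explicitly: the generator consumes
  `sim_config(seed = )` (cohort assignment uses `seed + 1`) and restores the
  caller's RNG state; the bootstrap takes its own seed.

## Validation scale and known limitations

The packaged Monte Carlo calibrations run at ~300 counties × 22 years with
treated cohorts of 60 and 40 (200 replications): under a null effect path
the overall conditional ATT is unbiased, its 95% CI covers zero ~95–97% of
the time, and the pre-trend Wald test rejects at ~5–7%. Cohorts of this
size are used for calibration because influence-function inference is
asymptotic in the number of treated counties. Effect-path recovery is
validated at the full study scale (2,927 counties, cohorts 36/19), where
the uniform event-study bands cover the true post-treatment path in ~97% of
replications.

Known limitation: with treated cohorts as small as the study's (19 counties
in the late cohort), uniform bands spanning *all* event times — including
far pre-treatment years estimated from that one small cohort — undercover
(~86–88% instead of 95% in our experiments; enlarging the cohorts to
300/150 restores ~94%). The studentized pre-period statistics have t-like
tails with ~20 degrees of freedom that the Rademacher multiplier
distribution understates. Inference on the post-treatment path and on the
overall ATT is well calibrated; conclusions that lean on the extreme
pre-period band edges with few treated counties should not be.

The pipeline (`run_pipeline()`) and the Monte Carlo harness
(`monte_carlo_study()`) tie the pieces together and write plain-text
artifacts (comparison table, event-study CSV, filter report, manifest);
figures are deliberately left to the user — the CSVs are the test surface.
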