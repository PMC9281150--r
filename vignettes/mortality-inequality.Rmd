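---
title: "Measuring the mortality gradient of retirement pensioners by pension income"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the mortality gradient of retirement pensioners by pension income}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penslife)
```

## The problem and the estimand

Richer pensioners tend to live longer than poorer ones, and the size and
trend of that gap matter for the actuarial fairness of public pension
systems. `penslife` quantifies this gradient for male retirement
pensioners whose only socioeconomic indicator is the initial amount of
their pension — a good proxy for earnings over the last working decades —
using two complementary indicators:

* **relative mortality**, the ratio of a pension-income (PI) group's
  death rate to the whole cohort's rate for the same age interval and
  period, and
* **period life expectancy** at ages 65 and 75 (LE65, LE75) by PI group,
  with confidence intervals and one-tailed tests of group differences.

The pipeline runs from individual administrative records: exclusion
cascade, PI classification, person-years tabulation, graduation of
age-specific rates, life tables, and the inequality summaries.

## Cohort selection and PI groups

The analysis population is male, general-regime retirement pensioners who
retired at the statutory age (65) or later. Everything else is removed by
`apply_exclusions()` in a fixed precedence order — invalid birth date,
female, non-retirement benefit, administrative error, benefit of a
deceased pensioner, early retirement, special scheme, other technical —
with a record that fails several rules counted once, in the first
matching category. That single-counting rule is a design choice: the
source tables this layout mirrors are conserved (initial = final + sum of
exclusions), and only one precedence-ordered counting reproduces a
conserved table. Unparseable or internally inconsistent rows are counted
as administrative errors rather than silently dropped.

Early retirement is defined as an exact retirement age below 65, matching
the statutory-age criterion. PI groups come from the legal minimum (Min)
and maximum (Max) benefits in force at retirement:

* Low: B ≤ Min
* Med-Low: Min < B ≤ 0.5·Max + 0.33·Min
* Med-High: 0.5·Max + 0.33·Min < B ≤ 0.75·Max
* High: B > 0.75·Max

The coefficient is 0.33 as legislated, not 1/3; boundaries are closed on
the upper side. The defaults (`pi_thresholds()`) are the 2018
single-pensioner values, Min = 657.60 and Max = 2617.53 EUR/month; the
single-pensioner minimum is used rather than the dependent-spouse one
(both are legal minima — the choice is configurable). Groups are fixed at
retirement and never reassigned: absolute cutoffs avoid the
quartile-migration artifacts of percentile grouping.

## Exposure and death tabulation

`build_table()` accrues person-years by *age last birthday* (the standard
demographic convention; the data themselves do not dictate one), from the
latest of pension start, period start and the 65th birthday, to the
earliest of death, pension end and period end. Intervals are half-open at
birthdays, so a death on an exact birthday contributes zero exposure at
the age just attained and the death is attributed to that age. Day counts
divide by 365.25, which absorbs leap days. Ages above 101 pool into 101,
the life-table closing age. Exposure is computed at day resolution even
though some administrative sources store pension dates at month/year
granularity; tabulation, not the data schema, decides the granularity.

One degenerate corner is worth noting: an exact-birthday death can put a
death into a cell with zero exposure, so "D = 0 wherever E = 0" holds
except on that measure-zero boundary.

## Graduation

Crude rates D_x/E_x are noisy at single ages, especially in the oldest
cells. The workhorse smoother, `pspline_graduate()`, is a penalized
B-spline Poisson regression: D_x ~ Poisson(E_x·exp(η_x)) with η_x a cubic
B-spline expansion (one interior knot per 2 ages), a second-order
difference penalty on the coefficients, and penalized IRLS iterated to a
relative coefficient change below 1e-6 (or a stabilized deviance, which
covers boundary cases such as all-zero death counts) with a 200-iteration
cap and explicit failure beyond it. The smoothing parameter λ minimizes
BIC = deviance + log(n)·ED over the log-spaced grid 10^(−4) … 10^8,
where ED is the effective dimension tr(H). These defaults mirror the
standard settings of penalized Poisson mortality smoothers; knot spacing,
degree, penalty order and λ are all arguments.

Two limits anchor the method and are tested: at λ→0 with a knot at every
age the fit reproduces the crude rates; at λ→∞ the order-2 penalty leaves
its null space, a straight line in log-rate — a Gompertz schedule.
Graduated central rates convert to death probabilities by
q = 1 − exp(−m), the constant-force-within-year convention; the
conversion is stated here because graduation produces central rates while
the life table consumes probabilities.

`beta_kernel_graduate()` is an independent cross-check: a kernel-weighted
average of crude rates with a beta kernel supported on the normalized age
interval [0, 1], whose shape adapts near the boundaries of the age range
(the reason to prefer it over a symmetric kernel on a bounded age
window). Bandwidth is user-set or chosen by exposure-weighted
leave-one-out cross-validation. The test suite checks that LE65 from the
two graduations of the same simulated schedule agrees within 1%.

Each (group, period) series is graduated independently, and the `Total`
series is graduated from its own pooled deaths and exposures rather than
by averaging group fits: pooled graduation keeps the Total series a
genuine rate schedule (exposure-weighting group *fits* would entangle
their smoothing artifacts). The alternative exposure-weighted denominator
remains available in `relative_mortality(total = "weighted")`, under
which the exposure-weighted mean of group ratios is exactly 1.

## Life tables, variances and tests

`build_life_table()` uses the standard single-age recursion with radix
100,000 and separation factor a_x = 0.5 below the closing age — the usual
convention at ages 65+, where deaths are near-uniform within the year.
The final age is an open interval: q is set to 1 and its person-years are
a_ω = 1/m_ω capped at 1.0, with the graduated central rate at the closing
age supplying m_ω. The cap keeps the closeout bounded when the supplied
terminal rate is small; in realistic schedules m(101) ≈ 2 and the cap
does not bind.

The variance of LE propagates per-age sampling variances through the
life-table linear form with weights l_x²[(1 − a_x) + e_{x+1}]², Chiang's
classical construction. Per-age variances are var(q_x) = q_x²(1 − q_x)/D_x
with the expected death count D_x = E_x·m_x in the denominator —
algebraically Chiang's binomial variance with person-years at risk as
trials. The open final age contributes no sampling term: its death
probability is 1 by construction and the survivors reaching it are a
negligible fraction of the radix. The adequacy of the whole substitution
is verified empirically, not assumed: the suite compares the Chiang 95%
CI width with a 500-replicate parametric bootstrap (Poisson resampling of
death counts at fixed exposures, life table rebuilt from the resampled
crude rates) and requires agreement within 15%. The parametric bootstrap
stands in for individual-level resampling because the two are
asymptotically equivalent for Poisson-distributed death counts while
keeping the suite's simulation sizes modest.

Differences between groups use the one-tailed normal test
z = (LE_a − LE_b)/√(var_a + var_b), flagged at z > 2.326 (1%),
1.645 (5%), 1.282 (10%). When a group's upper 95% bound exceeds a richer
group's lower bound by a wide margin, the 5% one-tailed test cannot
reject — the CI-overlap heuristic holds approximately by construction.

## Inequality summaries

Relative mortality per 5-year age group (65–69 … 80–84, 85+ pooling
85–101, plus a Total row) uses exposure-weighted bin rates
q_h = Σ E_x q_x / Σ E_x. Mortality improvements between periods are
100·(1 − Σw q_later / Σw q_earlier) with the *earlier* period's exposures
as weights — a fixed, Laspeyres-style standard, switchable to the later
period's since no convention is canonical; with microdata unavailable,
neither can be singled out, so both are implemented. The Low–High LE gap
trend is the OLS slope of the per-period gap on the period index.
Presentation tables round to 2 decimals; internal precision is full.

## The synthetic-data generator

`generate_records()` emulates the statistical structure the analysis
assumes, not any real person:

* **Mortality**: Gompertz–Makeham hazards μ(x) = a + b·cˣ per PI group.
  Death ages are drawn by inverse-CDF sampling on the closed-form
  cumulative hazard (interpolated on a 0.01-year grid), from the exact
  age at pension start. Defaults share a = 5·10⁻⁴/yr and c = 1.11 with
  group-specific b calibrated by root-finding so the true LE65 values are
  about 19.0, 19.8, 20.7 and 21.5 years — a ~2.5-year Low-to-High
  gradient of the magnitude reported for pensioner populations, inside
  the observed LE range. `true_life_expectancy()` integrates the survival
  function (step ≤ 0.01 year, to age 120) and is the recovery target for
  the pipeline.
* **Composition**: group weights default to the observed first-period
  exposure shares (15.05 / 48.01 / 17.79 / 19.15%); pension amounts are
  lognormal per group, truncated to the group's cutoff interval so
  ground-truth labels are exact and classifier tests are isolated from
  distributional overlap. The lognormal shape itself is a stand-in — the
  within-group benefit distribution is not documented anywhere we can
  draw on.
* **Observation window**: pension starts spread uniformly over the 40
  recruitment years ending at the window end, so 2005–2018 contains
  exposure at all ages 65–101; deaths after the window end are emitted as
  censored, emulating pensioners alive at the last data wave.
* **Contamination**: each record carries at most one defect, drawn
  multinomially at rates defaulting to the published cascade's
  first-period percentages. Every defect is *data-visible* (a female
  record, a missing birth date, inconsistent dates, a non-general regime,
  …) and also labelled in a hidden `defect_class` column, so filter
  counts can be audited against ground truth without the filter ever
  reading the label.
* Dates are emitted at day resolution, ISO-8601, with empty strings for
  missing values; identical configurations and seeds give byte-identical
  CSVs.

What the generator does **not** emulate: month/year-truncated pension
dates, within-group benefit–mortality correlation (mortality depends on
income only through the group), duplicate records, cohort trends within a
period, migration, or reporting delays. Passing tests therefore
demonstrate that the pipeline recovers what it assumes — group-wise
Gompertz–Makeham mortality with exact labels — not that it is robust to
every pathology of real administrative data.

## Numerical choices and degenerate inputs

* IRLS tolerance 1e-6 (relative coefficient change), 200 iterations,
  explicit error on non-convergence; grid points that fail during BIC
  search are skipped with the failure recorded by exclusion.
* Linear systems solve with a relaxed singularity tolerance because the
  saturated limit (knot per age, λ→0) is legitimately ill-conditioned;
  non-finite iterates are treated as singular fits.
* The beta-kernel weights are computed on the log scale and renormalized
  per evaluation age, so extreme bandwidths neither overflow nor lose the
  weights-sum-to-one property; as bandwidth → 0 the smoother returns the
  crude rates exactly at observed ages.
* Ages with zero exposure are excluded from fitting and their rates are
  interpolated from the fitted spline; at least 5 ages with positive
  exposure are required.
* An all-zero death series graduates to a near-zero schedule with a
  warning rather than an error.
* Feb-29 birthdays anniversary on Feb 28 in non-leap years.
* Empty record sets flow through the filter and tabulation as empty
  results with zero counts, not errors.

## Problem sizes used by the test suite

The suite's simulation sizes are the package's own choices: hazard
recovery is checked at 200,000 records (3-Poisson-SE bands at ages 70,
75, 80); LE recovery at ~50,000 records per PI group with a ±0.15-year
band against the closed-form truth; the engineered ~2.5-year gap must be
flagged at the 1% one-tailed level in at least 95% of 50 replicates of
two 50,000-record groups; CI calibration uses a 500-replicate parametric
bootstrap at 50,000 records. Smaller batches (2,000–20,000) exercise the
filter, tabulation and conservation properties.

## Known limitations

* Real pensioner microdata are access-restricted, so the published
  headline results can only be reproduced at the level of their printed
  aggregate arithmetic (shipped under `inst/extdata/`); the full pipeline
  is validated against synthetic ground truth instead.
* The variance of LE ignores smoothing-induced correlation between ages:
  Chiang's form treats the graduated q_x as independent estimates. The
  bootstrap comparison bounds the practical effect.
* The survivability decomposition of LE-gap changes (ex-ante/ex-post
  effects of rate declines) is out of scope, as is any comparison beyond
  accepting a user-supplied reference LE series.
* A single thresholds pair applies to all retirement years unless the
  user supplies a year-specific lookup; real Min/Max values change
  yearly.
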