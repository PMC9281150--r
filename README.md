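# penslife

Mortality inequality and period life tables for retirement pensioners by
pension-income level.

## What it is for

Administrative pension records are one of the few data sources that link
old-age mortality to lifetime income. `penslife` implements, as a reusable
R pipeline, the standard analysis a demographer or social-insurance
actuary runs on such records to quantify the socioeconomic mortality
gradient among male retirement pensioners:

1. **Cohort selection** — an auditable exclusion cascade (invalid birth
   dates, female records, non-retirement benefits, administrative errors,
   benefits of deceased pensioners, early retirees, special schemes, other
   technical defects), applied in a fixed precedence order so the filter
   report conserves counts.
2. **Pension-income (PI) classification** — four groups from the legal
   minimum (Min) and maximum (Max) benefits in force at retirement:
   Low ≤ Min; Med-Low in (Min, 0.5·Max + 0.33·Min]; Med-High in
   (0.5·Max + 0.33·Min, 0.75·Max]; High > 0.75·Max.
3. **Tabulation** — person-years exposure E and death counts D by single
   completed year of age (65–101, older pooled into 101), PI level and
   study period, with exposure split at birthdays and day counts divided
   by 365.25.
4. **Graduation** — penalized B-spline (P-spline) Poisson regression of
   D_x on age with offset log E_x, second-order difference penalty and
   BIC-selected smoothing; a discrete beta-kernel smoother is provided as
   an independent cross-check. Central rates convert to death
   probabilities by q = 1 − exp(−m).
5. **Period life tables** for ages 65–101 (radix 100,000, a_x = 0.5,
   open-age closeout), with life expectancy at 65 and 75 (LE65, LE75),
   Chiang-style variances, 95% confidence intervals and one-tailed
   z-tests of LE differences between PI groups
   (z = ΔLE / √(var_a + var_b); 1% / 5% / 10% flags).
6. **Inequality summaries** — relative mortality
   RM_h^m = q_h^m / q_h^T per 5-year age group h (a group's
   exposure-weighted rate over the whole cohort's), Low–High gaps,
   mortality improvements between periods
   (100·(1 − Σw·q_later / Σw·q_earlier)), and the linear trend of the
   Low–High LE gap across periods.

Because the underlying microdata (a 4% sample of social-security records)
are access-restricted, the package also ships a **synthetic record
generator**: income-group-dependent Gompertz–Makeham mortality
(μ(x) = a + b·cˣ), truncated-lognormal pension amounts per group, and
data-visible record defects at configurable rates, so the whole pipeline
can be exercised end-to-end and its parameter recovery verified against
closed-form ground truth (`true_life_expectancy()`).

## Worked example

```r
library(penslife)

cfg <- sim_config(50000, seed = 42,
                  group_weights = c("Low" = 0.25, "Med-Low" = 0.25,
                                    "Med-High" = 0.25, "High" = 0.25),
                  contamination_rates = c(female = 0.05,
                                          early_retirement = 0.02))
rec <- generate_records(cfg)
flt <- apply_exclusions(rec)
flt$report
#> Exclusion cascade: 50,000 initial records
#>   - invalid_birth_date                0  (0.00%)
#>   - female                        2,479  (4.96%)
#>   - non_retirement                    0  (0.00%)
#>   - administrative_error              0  (0.00%)
#>   - deceased_benefit                  0  (0.00%)
#>   - early_retirement                964  (1.93%)
#>   - special_scheme                    0  (0.00%)
#>   - other_technical                   0  (0.00%)
#>   = final cohort               46,557  (93.11%)

window <- list(period_def("W", "2005-01-01", "2018-12-31"))
tab <- build_table(flt$cohort, window)
res <- lapply(c("Low", "High"), function(g) {
  s <- tab[tab$pi_level == g, ]; s <- s[order(s$age), ]
  fit <- pspline_graduate(s$deaths, s$exposure, s$age)
  lt <- build_life_table(fit$q_grad, s$age, mx = fit$m_grad)
  list(le = le_at(lt, 65), var = chiang_variance(lt, s$exposure))
})
sprintf("LE65 Low = %.2f, High = %.2f years", res[[1]]$le, res[[2]]$le)
#> "LE65 Low = 18.98, High = 21.20 years"
test_le_difference(res[[2]]$le, res[[2]]$var, res[[1]]$le, res[[1]]$var)
#> DLE = 2.212 years (SE 0.200), z = 11.05 ***
```

The 2,479 female and 964 early-retirement records are the generator's
deliberate contamination, caught by the cascade; the ~2.2-year Low–High
LE65 difference recovers the generator's built-in ~2.5-year gradient
(here from one 50,000-record draw, of which ~11,600 land in each group)
and is highly significant on the one-tailed z-test.

The full pipeline — all stage CSVs, life tables, difference tests,
relative-mortality and improvement tables, figures and a JSON summary —
runs from a single config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "penslife"), "demo_out")
```

or from a shell:

```sh
Rscript inst/scripts/run_pipeline.R --config inst/extdata/demo_config.yaml --out demo_out
```

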