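test_that("identical config and seed give byte-identical output", {
  cfg <- sim_config(500, seed = 7)
  r1 <- generate_records(cfg)
  r2 <- generate_records(cfg)
  attr(r1, "config") <- attr(r2, "config") <- NULL
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_records(r1, f1); write_records(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_records(f1)
  expect_equal(rt$birth_date, r1$birth_date)
  expect_equal(rt$initial_pension_eur_month, r1$initial_pension_eur_month)
})

test_that("a defect-free all-male retire-at-65 batch passes the filter in full", {
  rec <- generate_records(clean_config(2000, seed = 3))
  expect_true(all(rec$defect_class == "none"))
  flt <- apply_exclusions(rec)
  expect_equal(attr(flt$report, "final"), 2000)
  expect_equal(sum(flt$report$excluded), 0)
})

test_that("defect class frequencies fall inside binomial 99% bounds", {
  n <- 50000
  rec <- generate_records(sim_config(n, seed = 11))
  rates <- default_contamination_rates()
  counts <- table(factor(rec$defect_class, levels = names(rates)))
  for (cl in names(rates)) {
    lo <- qbinom(0.005, n, rates[[cl]])
    hi <- qbinom(0.995, n, rates[[cl]])
    expect_gte(counts[[cl]], lo)
    expect_lte(counts[[cl]], hi)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(0), "positive count")
  expect_error(sim_config(10, group_weights = c("Low" = 0.5, "Med-Low" = 0.2,
                                                "Med-High" = 0.2,
                                                "High" = 0.2)),
               "sum to 1")
  expect_error(sim_config(10, contamination_rates = c(female = 1.2)),
               "\\[0, 1\\]")
})

test_that("empirical central death rates match the generating hazard", {
  # one-group cohort observed over a 30-year window; the crude rate at each
  # checked age must fall within 3 Poisson standard errors of mu(age)
  pars <- list(a = 0, b = 2.8e-5, c = 1.117)
  cfg <- one_group_config(200000, group = "Low", seed = 5,
                          period_span = c(1989L, 2018L),
                          gompertz_params = list(
                            "Low" = pars, "Med-Low" = pars,
                            "Med-High" = pars, "High" = pars))
  rec <- generate_records(cfg)
  flt <- apply_exclusions(rec)
  tab <- build_table(flt$cohort,
                     list(period_def("W", "1989-01-01", "2018-12-31")))
  tot <- tab[tab$pi_level == "Total", ]
  for (age in c(70, 75, 80)) {
    row <- tot[tot$age == age, ]
    mu <- gm_hazard(age + 0.5, pars)     # hazard at the interval midpoint
    crude <- row$deaths / row$exposure
    se <- sqrt(row$deaths) / row$exposure
    expect_lt(abs(crude - mu), 3 * se)
  }
})

test_that("true_life_expectancy matches closed forms and a finer grid", {
  # constant hazard: LE = 1/a (exponential lifetime)
  const <- list(a = 0.5, b = 0, c = 1.1)
  expect_equal(true_life_expectancy(const, 65), 1 / 0.5, tolerance = 1e-4)
  # doubling the constant hazard halves LE
  expect_equal(true_life_expectancy(list(a = 1, b = 0, c = 1.1), 65),
               true_life_expectancy(const, 65) / 2, tolerance = 1e-4)
  # Gompertz: step 0.01 agrees with an independent step-0.001 integration
  pars <- list(a = 0, b = 2.8e-5, c = 1.117)
  fine <- {
    t <- seq(0, 55, by = 0.001)
    S <- exp(-(pars$b / log(pars$c)) * (pars$c^(65 + t) - pars$c^65))
    sum((S[-1] + S[-length(S)]) / 2) * 0.001
  }
  expect_equal(true_life_expectancy(pars, 65), fine, tolerance = 1e-4)
  expect_error(true_life_expectancy(list(a = 0, b = 1e-5, c = 0.9)),
               "must exceed 1")
  expect_error(true_life_expectancy(list(a = 0.1, b = -1, c = 1.1)),
               "nonnegative")
})
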