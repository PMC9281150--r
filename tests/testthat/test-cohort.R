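test_that("PI classification boundaries follow the cutoff rules literally", {
  th <- pi_thresholds(min_eur = 657.60, max_eur = 2617.53)
  # Med-Low/Med-High cut, hand-checked: 0.5*2617.53 + 0.33*657.60
  #   = 1308.765 + 217.008 = 1525.773
  cut2 <- 1525.773
  cut3 <- 0.75 * 2617.53          # 1963.1475
  expect_equal(as.character(classify_pi(657.60, th)), "Low")
  expect_equal(as.character(classify_pi(657.61, th)), "Med-Low")
  expect_equal(as.character(classify_pi(cut2, th)), "Med-Low")
  expect_equal(as.character(classify_pi(cut2 + 0.001, th)), "Med-High")
  expect_equal(as.character(classify_pi(cut3, th)), "Med-High")
  expect_equal(as.character(classify_pi(cut3 + 0.001, th)), "High")
  expect_equal(as.character(classify_pi(0, th)), "Low")
  expect_error(classify_pi(-1, th), "nonnegative")
  expect_error(pi_thresholds(min_eur = 100, max_eur = 50), "Min < Max")
})

test_that("classification partitions and is monotone for any thresholds", {
  set.seed(42)
  for (i in 1:20) {
    mn <- runif(1, 100, 1000)
    th <- pi_thresholds(min_eur = mn, max_eur = mn * runif(1, 1.5, 6))
    b <- sort(runif(200, 0, 4000))
    lv <- classify_pi(b, th)
    expect_false(any(is.na(lv)))                 # exactly one group each
    expect_true(all(diff(as.integer(lv)) >= 0))  # nondecreasing in benefit
  }
})

test_that("exclusion counts reproduce ground-truth defect labels", {
  cfg <- sim_config(10000, seed = 9,
                    contamination_rates = c(
                      invalid_birth_date = 0.02, female = 0.3,
                      non_retirement = 0.1, administrative_error = 0.02,
                      deceased_benefit = 0.03, early_retirement = 0.1,
                      special_scheme = 0.05, other_technical = 0.01))
  rec <- generate_records(cfg)
  flt <- apply_exclusions(rec)
  truth <- table(factor(rec$defect_class,
                        levels = c(flt$report$category, "none")))
  for (i in seq_len(nrow(flt$report))) {
    expect_equal(flt$report$excluded[i],
                 unname(truth[[flt$report$category[i]]]),
                 info = flt$report$category[i])
  }
  expect_equal(attr(flt$report, "final"), unname(truth[["none"]]))
})

test_that("filter reports conserve counts on random contaminated batches", {
  for (seed in 1:5) {
    set.seed(seed)
    rates <- runif(8, 0, 0.1)
    names(rates) <- c("invalid_birth_date", "female", "non_retirement",
                      "administrative_error", "deceased_benefit",
                      "early_retirement", "special_scheme",
                      "other_technical")
    rec <- generate_records(sim_config(2000, seed = seed,
                                       contamination_rates = rates))
    flt <- apply_exclusions(rec)
    expect_equal(attr(flt$report, "initial"),
                 attr(flt$report, "final") + sum(flt$report$excluded))
    # percentages recompute from counts to 2 decimals
    expect_equal(flt$report$pct,
                 round(100 * flt$report$excluded /
                         attr(flt$report, "initial"), 2))
  }
})

test_that("empty input yields an empty cohort and all-zero report", {
  rec <- generate_records(clean_config(5, seed = 1))[0, ]
  flt <- apply_exclusions(rec)
  expect_equal(nrow(flt$cohort), 0)
  expect_equal(attr(flt$report, "initial"), 0L)
  expect_true(all(flt$report$excluded == 0))
})

test_that("year-indexed thresholds classify by retirement year", {
  tbl <- pi_thresholds_table(
    pi_thresholds(min_eur = 500, max_eur = 2000, year = 2000L),
    pi_thresholds(min_eur = 657.60, max_eur = 2617.53, year = 2010L))
  rec <- generate_records(clean_config(4, seed = 6))
  rec$initial_pension_eur_month <- rep(600, 4)   # Low pre-2010, Med-Low after
  rec$pension_start_date <- as.Date(c("2005-06-01", "2012-06-01",
                                      "1995-06-01", "2018-06-01"))
  rec$birth_date <- rec$pension_start_date - ceiling(65.1 * 365.25)
  rec$death_date <- rec$pension_end_date <- as.Date(NA)
  flt <- apply_exclusions(rec, thresholds = tbl)
  expect_equal(as.character(flt$cohort$pi_level),
               c("Med-Low", "Low", "Med-Low", "Low"))
  expect_error(pi_thresholds_table(
    pi_thresholds(year = 2000L), pi_thresholds(year = 2000L)),
    "duplicate")
})

test_that("multi-defect records are counted once, in the first category", {
  rec <- generate_records(clean_config(4, seed = 2))
  rec$sex[1] <- "female"; rec$regime[1] <- "self_employed"  # two defects
  rec$birth_date[2] <- NA; rec$sex[2] <- "female"           # two defects
  flt <- apply_exclusions(rec)
  expect_equal(attr(flt$report, "final"), 2)
  expect_equal(flt$report$excluded[flt$report$category == "female"], 1)
  expect_equal(
    flt$report$excluded[flt$report$category == "invalid_birth_date"], 1)
  expect_equal(
    flt$report$excluded[flt$report$category == "special_scheme"], 0)
})
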