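ages_std <- 65:101

test_that("constant-hazard data graduate to rates near the generating value", {
  set.seed(101)
  E <- rep(10000, length(ages_std))
  D <- rpois(length(ages_std), E * 0.02)
  fit <- pspline_graduate(D, E, ages_std)
  expect_true(all(fit$m_grad > 0.015 & fit$m_grad < 0.025))
  expect_equal(fit$q_grad, 1 - exp(-fit$m_grad))
})

test_that("huge smoothing drives log-rates to a straight line in age", {
  set.seed(102)
  E <- rep(5000, length(ages_std))
  D <- rpois(length(ages_std), E * 1e-5 * 1.11^ages_std)
  fit <- pspline_graduate(D, E, ages_std, lambda = 1e8)
  eta <- log(fit$m_grad)
  r2 <- summary(lm(eta ~ ages_std))$r.squared
  expect_gt(r2, 0.999)
})

test_that("the saturated low-penalty limit reproduces crude rates", {
  set.seed(103)
  E <- rep(8000, length(ages_std))
  D <- rpois(length(ages_std), E * 1e-5 * 1.11^ages_std)
  fit <- pspline_graduate(D, E, ages_std, knot_spacing = 1, lambda = 1e-8)
  crude <- D / E
  pos <- D > 0
  expect_equal(fit$m_grad[pos], crude[pos], tolerance = 1e-3)
})

test_that("graduation is deterministic and balances fitted deaths", {
  set.seed(104)
  E <- round(runif(length(ages_std), 2000, 20000))
  D <- rpois(length(ages_std), E * 1e-5 * 1.11^ages_std)
  f1 <- pspline_graduate(D, E, ages_std)
  f2 <- pspline_graduate(D, E, ages_std)
  expect_identical(f1$m_grad, f2$m_grad)
  expect_identical(attr(f1, "lambda"), attr(f2, "lambda"))
  # Poisson score balance: fitted deaths match observed within 0.5%
  expect_lt(abs(sum(E * f1$m_grad) - sum(D)) / sum(D), 0.005)
})

test_that("graduation input contracts are enforced", {
  expect_error(pspline_graduate(c(1, 2), c(10, 10), c(65, 66)),
               "at least 5 ages")
  expect_error(pspline_graduate(rep(0, 10), rep(0, 10), 65:74),
               "at least 5 ages")
  expect_warning(pspline_graduate(rep(0, 10), rep(100, 10), 65:74,
                                  lambda = 10),
                 "all death counts are zero")
})

test_that("beta kernel reproduces constant schedules and the crude limit", {
  E <- rep(1000, length(ages_std))
  D <- rep(20, length(ages_std))            # constant crude rate 0.02
  fit <- beta_kernel_graduate(D, E, ages_std, bandwidth = 0.3)
  expect_equal(fit$m_grad, rep(0.02, length(ages_std)), tolerance = 1e-12)
  set.seed(105)
  D2 <- rpois(length(ages_std), E * 0.03)
  near0 <- beta_kernel_graduate(D2, E, ages_std, bandwidth = 1e-4)
  expect_equal(near0$m_grad, D2 / E, tolerance = 1e-6)
  expect_error(beta_kernel_graduate(D2, E, ages_std, bandwidth = 0),
               "positive")
})

test_that("P-spline and beta-kernel graduations agree on Gompertz data", {
  # cross-method robustness: LE at 65 from the two graduations of the same
  # simulated schedule differs by under 1%
  rec <- generate_records(one_group_config(50000, group = "Med-Low",
                                           seed = 21))
  flt <- apply_exclusions(rec)
  tab <- build_table(flt$cohort,
                     list(period_def("W", "2005-01-01", "2018-12-31")))
  s <- tab[tab$pi_level == "Total", ]
  s <- s[order(s$age), ]
  fp <- pspline_graduate(s$deaths, s$exposure, s$age)
  fb <- beta_kernel_graduate(s$deaths, s$exposure, s$age)
  le_p <- le_at(build_life_table(fp$q_grad, s$age, mx = fp$m_grad), 65)
  le_b <- le_at(build_life_table(fb$q_grad, s$age, mx = fb$m_grad), 65)
  expect_lt(abs(le_p - le_b) / le_p, 0.01)
})

test_that("graduate_table covers every group-period series", {
  rec <- generate_records(clean_config(20000, seed = 22))
  flt <- apply_exclusions(rec)
  tab <- build_table(flt$cohort,
                     list(period_def("P1", "2005-01-01", "2011-12-31"),
                          period_def("P2", "2012-01-01", "2018-12-31")))
  grad <- graduate_table(tab)
  expect_setequal(unique(grad$pi_level), c(pi_levels(), "Total"))
  expect_setequal(unique(grad$period), c("P1", "P2"))
  expect_true(all(grad$m_grad >= 0))
  expect_true(all(grad$q_grad >= 0 & grad$q_grad <= 1))
})
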