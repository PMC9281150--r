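# Small constructed rate/exposure tables for exact arithmetic checks.
make_grad <- function(q_by_group, period = "P1", ages = 65:101) {
  rows <- lapply(names(q_by_group), function(g) {
    data.frame(age = ages, pi_level = g, period = period,
               m_grad = q_by_group[[g]], q_grad = q_by_group[[g]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

make_tab <- function(E_by_group, D = 0, period = "P1", ages = 65:101) {
  rows <- lapply(names(E_by_group), function(g) {
    data.frame(age = ages, pi_level = g, period = period,
               exposure = E_by_group[[g]], deaths = D,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("relative mortality reproduces definitional ratios", {
  q <- list("Low" = 0.03, "Med-Low" = 0.02, "Med-High" = 0.02,
            "High" = 0.02, "Total" = 0.02)
  E <- list("Low" = 1, "Med-Low" = 1, "Med-High" = 1, "High" = 1,
            "Total" = 4)
  rm <- relative_mortality(make_grad(q), make_tab(E))
  # a group at the overall rate has RM exactly 1.00
  expect_equal(rm$rm[rm$pi_level == "Med-Low"], rep(1, 6))
  # q_group = 0.03 vs q_total = 0.02 gives 1.5 in every bin
  expect_equal(rm$rm[rm$pi_level == "Low"], rep(1.5, 6))
  dif <- dif_low_high(rm)
  expect_equal(dif$dif_low_high, rep(0.5, 6))
})

test_that("exposure-weighted mean RM is 1 under the weighted total", {
  set.seed(51)
  ages <- 65:101
  for (i in 1:5) {
    q <- list(); E <- list()
    for (g in pi_levels()) {
      q[[g]] <- runif(length(ages), 0.005, 0.4)
      E[[g]] <- runif(length(ages), 10, 1000)
    }
    q$Total <- rep(0, length(ages))     # unused under total = "weighted"
    E$Total <- Reduce(`+`, E[pi_levels()])
    rm <- relative_mortality(make_grad(q), make_tab(E), total = "weighted")
    for (b in unique(rm$age_group)) {
      sub <- rm[rm$age_group == b, ]
      scheme <- age_group_scheme()
      w <- vapply(pi_levels(), function(g) {
        if (b == "Total") sum(E[[g]])
        else sum(E[[g]][scheme$bin(ages) == b])
      }, 0)
      expect_equal(sum(w * sub$rm[match(pi_levels(), sub$pi_level)]) /
                     sum(w), 1, tolerance = 1e-6)
    }
  }
})

test_that("RM is invariant to a common rescaling of all rates", {
  set.seed(52)
  ages <- 65:101
  q <- list(); E <- list()
  for (g in c(pi_levels(), "Total")) {
    q[[g]] <- runif(length(ages), 0.01, 0.3)
    E[[g]] <- runif(length(ages), 10, 1000)
  }
  rm1 <- relative_mortality(make_grad(q), make_tab(E))
  q2 <- lapply(q, function(x) 2 * x)
  rm2 <- relative_mortality(make_grad(q2), make_tab(E))
  expect_equal(rm1$rm, rm2$rm, tolerance = 1e-12)
})

test_that("mortality improvement arithmetic follows the sign convention", {
  ages <- 65:101
  q <- list("Low" = rep(0.05, 37), "High" = rep(0.04, 37))
  E <- list("Low" = rep(100, 37), "High" = rep(100, 37))
  ge <- make_grad(q, "P1")
  tab <- make_tab(E, period = "P1")
  # identical rates: zero improvement
  imp0 <- mortality_improvement(ge, make_grad(q, "P2"), tab, "P1", "P2")
  expect_equal(imp0$improvement_pct, rep(0, nrow(imp0)))
  # halved rates: +50%
  qh <- lapply(q, function(x) x / 2)
  imp1 <- mortality_improvement(ge, make_grad(qh, "P2"), tab, "P1", "P2")
  expect_equal(imp1$improvement_pct, rep(50, nrow(imp1)))
  # rates scaled by 0.9 for High only: High improves 10%, Low 0%
  q9 <- q; q9$High <- q$High * 0.9
  imp2 <- mortality_improvement(ge, make_grad(q9, "P2"), tab, "P1", "P2")
  expect_equal(imp2$improvement_pct[imp2$pi_level == "High"],
               rep(10, 6), tolerance = 1e-12)
  expect_equal(imp2$improvement_pct[imp2$pi_level == "Low"], rep(0, 6))
  # a rate increase reports a negative value (deterioration)
  qup <- q; qup$Low <- q$Low * 1.2
  imp3 <- mortality_improvement(ge, make_grad(qup, "P2"), tab, "P1", "P2")
  expect_true(all(imp3$improvement_pct[imp3$pi_level == "Low"] < 0))
})

test_that("LE gap trends recover exact slopes", {
  eq <- data.frame(period = rep(c("P1", "P2"), each = 2),
                   pi_level = rep(c("Low", "High"), 2),
                   le = rep(20, 4))
  t0 <- gap_trend(eq)
  expect_equal(t0$gaps$gap, c(0, 0))
  expect_equal(t0$slope, 0)
  # two observed gaps 1.49 and 2.58 one period apart: slope 1.09
  t1 <- gap_trend(data.frame(period = c("P1", "P3"), gap = c(1.49, 2.58)))
  expect_equal(t1$slope, 1.09, tolerance = 1e-12)
  t2 <- gap_trend(data.frame(period = c("P1", "P2", "P3"), gap = c(1, 2, 3)))
  expect_equal(t2$slope, 1.0, tolerance = 1e-12)
  expect_error(gap_trend(data.frame(period = "P1", gap = 1)),
               "at least 2 periods")
})
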