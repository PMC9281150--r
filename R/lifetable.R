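#' Build a complete period life table
#'
#' Standard single-age period life-table recursion on ages 65-101 (or any
#' contiguous integer range) with separation factor `a_x = 0.5` below the
#' closing age. The last age is treated as an open interval: its death
#' probability is set to 1 and its person-years use `a_omega = 1 / m_omega`
#' capped at 1.0, where `m_omega` is the supplied central rate at the
#' closing age (when `mx` is not supplied, `q_omega` itself stands in for
#' `m_omega`).
#'
#' @param qx Death probabilities in `[0, 1]` over `ages`.
#' @param ages Contiguous integer ages, default `65:101`.
#' @param mx Optional central rates over `ages`; only the last value is
#'   used, for the open-interval closeout.
#' @param radix Starting cohort size `l_65` (default 100,000).
#' @return Object of class `life_table`: a data.frame with columns
#'   `age, q, a, l, d, L, T, e` and attributes `radix`, `m_last`.
#' @export
build_life_table <- function(qx, ages = 65:101, mx = NULL, radix = 1e5) {
  n <- length(ages)
  stopifnot(length(qx) == n, n >= 2, all(diff(ages) == 1))
  if (any(is.na(qx)) || any(qx < 0) || any(qx > 1))
    stop("all death probabilities must lie in [0, 1]")
  if (!is.null(mx)) stopifnot(length(mx) == n)
  q <- qx
  q[n] <- 1                                  # open-interval closeout
  m_last <- if (!is.null(mx)) mx[n] else qx[n]
  a <- rep(0.5, n)
  a[n] <- if (is.finite(m_last) && m_last > 0) min(1 / m_last, 1) else 1

  l <- radix * cumprod(c(1, 1 - q[-n]))
  d <- l * q
  L <- l - (1 - a) * d
  T <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T / l, 0)
  structure(data.frame(age = ages, q = q, a = a, l = l, d = d,
                       L = L, T = T, e = e),
            radix = radix, m_last = m_last,
            class = c("life_table", "data.frame"))
}

#' Remaining life expectancy at an exact age from a life table
#'
#' @param lt A [build_life_table()] result.
#' @param age Age present in the table.
#' @return `e_x` in years.
#' @export
le_at <- function(lt, age) {
  i <- match(age, lt$age)
  if (is.na(i)) stop("age ", age, " not in the life table")
  lt$e[i]
}

#' Chiang-style variance of life expectancy
#'
#' Variance of `e_x` by propagating per-age sampling variances of the
#' death probabilities through the life-table linear form. Chiang's
#' estimator `var(q_x) = q_x^2 (1 - q_x) / D_x` is used with the expected
#' death count `D_x = E_x m_x` in the denominator (equivalently, binomial
#' variance with the person-years at risk as trials); the per-age terms
#' are weighted by `l_x^2 [(1 - a_x) + e_{x+1}]^2`. The open
#' final age contributes no sampling term (its death probability is 1 by
#' construction and the survivors reaching it are a negligible fraction of
#' the radix at these ages). Exposures enter as person-years; doubling
#' them halves the variance.
#'
#' @param lt A [build_life_table()] result.
#' @param exposures Person-years by age, aligned with `lt$age`.
#' @param start_age Age at which the LE variance is wanted (default 65).
#' @return Variance of LE at `start_age`, in years squared.
#' @export
chiang_variance <- function(lt, exposures, start_age = 65) {
  n <- nrow(lt)
  stopifnot(length(exposures) == n)
  s <- match(start_age, lt$age)
  if (is.na(s)) stop("start_age not in the life table")
  if (all(exposures[s:n] <= 0))
    stop("no exposure at or above start_age; variance undefined")
  m <- ifelse(lt$L > 0, lt$d / lt$L, 0)     # table-consistent central rates
  deaths_hat <- exposures * m
  var_q <- ifelse(deaths_hat > 0,
                  lt$q^2 * (1 - lt$q) / deaths_hat, 0)
  contrib <- numeric(n)
  idx <- s:(n - 1)
  if (length(idx))
    contrib[idx] <- lt$l[idx]^2 *
      ((1 - lt$a[idx]) + lt$e[idx + 1])^2 * var_q[idx]
  sum(contrib[s:n]) / lt$l[s]^2
}

#' Life expectancy summary with confidence intervals
#'
#' Convenience wrapper: builds the life table from graduated rates, and
#' returns LE with Chiang variance and a normal-approximation 95% CI at
#' each requested age.
#'
#' @param qx,mx Graduated death probabilities and central rates over
#'   `ages`.
#' @param exposures Person-years by age.
#' @param ages Integer ages (default `65:101`).
#' @param at Ages at which LE is summarised (default `c(65, 75)`).
#' @param level CI coverage (default 0.95).
#' @return Data frame with columns `age, le, var, se, ci_lo, ci_hi`.
#' @export
le_summary <- function(qx, mx, exposures, ages = 65:101, at = c(65, 75),
                       level = 0.95) {
  lt <- build_life_table(qx, ages, mx = mx)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(at, function(a) {
    le <- le_at(lt, a)
    v <- chiang_variance(lt, exposures, start_age = a)
    se <- sqrt(v)
    data.frame(age = a, le = le, var = v, se = se,
               ci_lo = le - zq * se, ci_hi = le + zq * se)
  })
  do.call(rbind, rows)
}

#' One-tailed test of a life-expectancy difference
#'
#' Tests the null that two groups' LE at the same age are equal against the
#' alternative that group `a`'s is higher: `z = (LE_a - LE_b) /
#' sqrt(var_a + var_b)`, flagged `***` when `z > 2.326` (1%), `**` when
#' `z > 1.645` (5%), `*` when `z > 1.282` (10%).
#'
#' @param le_a,le_b Point estimates of LE (years).
#' @param var_a,var_b Their variances (years squared).
#' @param age,period Optional labels; when both sides carry them they must
#'   match (use the `age_a`/`age_b` form via attributes is not supported -
#'   pass scalars).
#' @return Object of class `le_difference`: list with `dle`, `se`, `z`,
#'   `significance` (`"***"`, `"**"`, `"*"` or `""`), `age`, `period`.
#' @export
test_le_difference <- function(le_a, var_a, le_b, var_b,
                               age = NA, period = NA) {
  dle <- le_a - le_b
  se <- sqrt(var_a + var_b)
  z <- if (se > 0) dle / se else 0
  sig <- if (z > 2.326) "***" else if (z > 1.645) "**" else
    if (z > 1.282) "*" else ""
  structure(list(dle = dle, se = se, z = z, significance = sig,
                 age = age, period = period),
            class = "le_difference")
}

#' @export
print.le_difference <- function(x, ...) {
  cat(sprintf("DLE = %.3f years (SE %.3f), z = %.2f %s\n",
              x$dle, x$se, x$z, x$significance))
  invisible(x)
}

#' Compare LE between two labelled group summaries
#'
#' Wrapper over [test_le_difference()] that checks the two [le_summary()]
#' rows refer to the same age (and period label when given).
#'
#' @param summary_a,summary_b One-row data.frames with columns `age, le,
#'   var` (as returned by [le_summary()]), `a` being the putatively
#'   longer-lived group.
#' @param period_a,period_b Optional period labels; must match when given.
#' @return An `le_difference` object.
#' @export
compare_le <- function(summary_a, summary_b,
                       period_a = NA, period_b = NA) {
  if (summary_a$age != summary_b$age)
    stop("LE summaries refer to different ages (",
         summary_a$age, " vs ", summary_b$age, ")")
  if (!is.na(period_a) && !is.na(period_b) && period_a != period_b)
    stop("LE summaries refer to different periods (",
         period_a, " vs ", period_b, ")")
  test_le_difference(summary_a$le, summary_a$var,
                     summary_b$le, summary_b$var,
                     age = summary_a$age, period = period_a)
}
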