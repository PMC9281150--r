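# Graduation of crude age-specific death rates.
#
# The workhorse is a penalized B-spline (P-spline) Poisson regression:
# deaths D_x ~ Poisson(E_x exp(eta_x)) with eta_x a cubic B-spline
# expansion in age, a second-order difference penalty on the coefficients,
# and the smoothing parameter chosen by BIC on a log-spaced grid. The
# discrete beta-kernel smoother is an independent method used as a
# robustness cross-check.

bspline_basis <- function(ages, xl, xr, knot_spacing = 2, degree = 3) {
  ndx <- max(1L, ceiling((xr - xl) / knot_spacing))
  dx <- (xr - xl) / ndx
  knots <- seq(xl - degree * dx, xr + degree * dx, by = dx)
  splines::splineDesign(knots, x = ages, ord = degree + 1, outer.ok = TRUE)
}

diff_penalty <- function(ncoef, pord = 2) {
  D <- diff(diag(ncoef), differences = pord)
  crossprod(D)
}

pois_deviance <- function(D, mu) {
  r <- mu - D
  pos <- D > 0
  r[pos] <- r[pos] + D[pos] * log(D[pos] / mu[pos])
  2 * sum(r)
}

# one penalized IRLS fit at fixed lambda; returns coefficients, effective
# dimension, deviance and convergence info
pspline_fit_lambda <- function(D, E, B, P, lambda, tol = 1e-6, maxit = 200) {
  eta <- log(pmax(D, 0.5) / E)            # crude log-rates as the start
  theta <- NULL
  dev_old <- Inf
  conv <- FALSE; it <- 0
  while (it < maxit) {
    it <- it + 1
    mu <- pmax(E * exp(eta), 1e-12)
    z <- eta + (D - mu) / mu
    BtW <- t(B * mu)
    G <- BtW %*% B + lambda * P
    theta_new <- tryCatch(solve(G, BtW %*% z, tol = 1e-30),
                          error = function(e) NULL)
    if (is.null(theta_new) || any(!is.finite(theta_new)))
      return(list(converged = FALSE, singular = TRUE, iterations = it))
    delta <- if (is.null(theta)) Inf else
      max(abs(theta_new - theta) / (abs(theta) + 1e-6))
    if (!is.finite(delta) && !is.null(theta))
      return(list(converged = FALSE, singular = TRUE, iterations = it))
    theta <- drop(theta_new)
    eta <- drop(B %*% theta)
    dev <- pois_deviance(D, pmax(E * exp(eta), 1e-12))
    # converged when either the coefficients or the deviance stabilise
    # (the deviance criterion covers boundary cases such as all-zero
    # deaths, where the log-rates drift to -Inf at a vanishing deviance)
    if (delta < tol || abs(dev_old - dev) < tol * (abs(dev) + 0.1)) {
      conv <- TRUE; break
    }
    dev_old <- dev
  }
  mu <- pmax(E * exp(eta), 1e-12)
  BtW <- t(B * mu)
  G <- BtW %*% B + lambda * P
  ed <- sum(diag(solve(G, BtW %*% B, tol = 1e-30)))
  dev <- pois_deviance(D, mu)
  list(theta = theta, ed = ed, deviance = dev,
       converged = conv, singular = FALSE, iterations = it)
}

#' P-spline Poisson graduation of death rates
#'
#' Fits deaths `D_x ~ Poisson(E_x exp(eta_x))` with `eta_x` a cubic
#' B-spline expansion over age (one interior knot per `knot_spacing` ages)
#' and a second-order difference penalty on the spline coefficients.
#' Penalized IRLS is iterated to a relative coefficient change below `tol`;
#' the smoothing parameter is chosen by minimizing
#' `BIC = deviance + log(n) * ED` over a log-spaced grid (unless `lambda`
#' is given). Graduated central rates are `m_x = exp(eta_x)`; death
#' probabilities use the constant-force-within-year conversion
#' `q_x = 1 - exp(-m_x)`.
#'
#' Ages with zero exposure are excluded from the fit and their rates are
#' interpolated from the fitted spline. With an order-2 penalty, the limit
#' `lambda -> Inf` is a straight line in log-rate (Gompertz-like), and
#' `lambda -> 0` with knots at every age reproduces the crude rates.
#'
#' @param deaths,exposures Nonnegative vectors over `ages` (`exposures` in
#'   person-years); at least 5 ages must have positive exposure.
#' @param ages Integer ages of the schedule.
#' @param knot_spacing Ages per interior knot interval (default 2).
#' @param degree B-spline degree (default 3, cubic).
#' @param pord Order of the difference penalty (default 2).
#' @param lambda Fixed smoothing parameter; `NULL` selects by BIC.
#' @param lambda_grid Log-spaced candidate grid for BIC selection.
#' @param tol IRLS convergence tolerance on relative coefficient change.
#' @param maxit Maximum IRLS iterations (explicit failure beyond it).
#' @return Object of class `graduated_rates`: a data.frame with columns
#'   `age, m_grad, q_grad` and attributes `lambda`, `criterion` (BIC at the
#'   chosen lambda), `ed`, `iterations`, `method`.
#' @export
pspline_graduate <- function(deaths, exposures, ages,
                             knot_spacing = 2, degree = 3, pord = 2,
                             lambda = NULL,
                             lambda_grid = 10^seq(-4, 8, by = 0.25),
                             tol = 1e-6, maxit = 200) {
  stopifnot(length(deaths) == length(ages),
            length(exposures) == length(ages))
  use <- exposures > 0
  if (sum(use) < 5)
    stop("need at least 5 ages with positive exposure")
  if (all(deaths[use] == 0))
    warning("all death counts are zero; graduated rates come from the ",
            "penalized fit alone")
  xl <- min(ages); xr <- max(ages)
  B_all <- bspline_basis(ages, xl, xr, knot_spacing, degree)
  B <- B_all[use, , drop = FALSE]
  P <- diff_penalty(ncol(B), pord)
  D <- deaths[use]; E <- exposures[use]

  fit_one <- function(lam) pspline_fit_lambda(D, E, B, P, lam, tol, maxit)

  if (is.null(lambda)) {
    n_used <- sum(use)
    best <- NULL; best_bic <- Inf; best_lam <- NA_real_
    for (lam in lambda_grid) {
      f <- fit_one(lam)
      if (f$singular || !f$converged) next
      bic <- f$deviance + log(n_used) * f$ed
      if (bic < best_bic) { best <- f; best_bic <- bic; best_lam <- lam }
    }
    if (is.null(best))
      stop("P-spline graduation failed to converge for every candidate ",
           "smoothing parameter (grid of ", length(lambda_grid), ")")
    fit <- best; lambda <- best_lam; crit <- best_bic
  } else {
    if (lambda < 0) stop("lambda must be nonnegative")
    fit <- fit_one(lambda)
    if (fit$singular)
      stop("penalized system is singular at lambda = ", lambda)
    if (!fit$converged)
      stop(sprintf(paste0("IRLS did not converge in %d iterations ",
                          "(lambda = %g); last relative change above %g"),
                   maxit, lambda, tol))
    crit <- fit$deviance + log(sum(use)) * fit$ed
  }

  m <- drop(exp(B_all %*% fit$theta))
  out <- data.frame(age = ages, m_grad = m, q_grad = 1 - exp(-m))
  structure(out, lambda = lambda, criterion = crit, ed = fit$ed,
            iterations = fit$iterations, method = "pspline",
            class = c("graduated_rates", "data.frame"))
}

#' Discrete beta-kernel graduation of death rates
#'
#' Graduates crude rates `D_x / E_x` by a kernel-weighted average with a
#' beta kernel supported on the normalized age interval `[0, 1]`, which
#' adapts its shape near the boundaries of the age range. At evaluation age
#' `x` the weight of observation `x_i` is the beta density with shapes
#' `u_x / h + 1` and `(1 - u_x) / h + 1` evaluated at `u_i` (normalized
#' positions, bandwidth `h`). As `h -> 0` the graduated rates reproduce the
#' crude rates; a constant crude schedule is reproduced exactly for any
#' bandwidth (weights sum to one). The bandwidth is user-set or chosen by
#' leave-one-out cross-validation weighted by exposure.
#'
#' @inheritParams pspline_graduate
#' @param bandwidth Positive smoothing bandwidth on the normalized age
#'   scale; `NULL` selects by cross-validation.
#' @param bandwidth_grid Candidate grid for cross-validation.
#' @return Object of class `graduated_rates` (columns `age, m_grad,
#'   q_grad`; attributes `bandwidth`, `criterion`, `method`).
#' @export
beta_kernel_graduate <- function(deaths, exposures, ages, bandwidth = NULL,
                                 bandwidth_grid = 10^seq(-2.5, -0.5,
                                                         by = 0.1)) {
  stopifnot(length(deaths) == length(ages),
            length(exposures) == length(ages))
  use <- exposures > 0
  if (sum(use) < 5)
    stop("need at least 5 ages with positive exposure")
  if (!is.null(bandwidth) && bandwidth <= 0)
    stop("bandwidth must be positive")
  x_obs <- ages[use]
  r <- deaths[use] / exposures[use]
  w_exp <- exposures[use]
  xl <- min(ages); xr <- max(ages)
  u_obs <- (x_obs - xl) / (xr - xl)

  weight_matrix <- function(h, u_eval) {
    # rows: evaluation points; columns: observations (log scale for
    # numerical safety at small h)
    W <- matrix(0, length(u_eval), length(u_obs))
    for (j in seq_along(u_eval)) {
      lw <- stats::dbeta(u_obs, u_eval[j] / h + 1,
                         (1 - u_eval[j]) / h + 1, log = TRUE)
      lw <- lw - max(lw)
      w <- exp(lw)
      W[j, ] <- w / sum(w)
    }
    W
  }

  cv_score <- function(h) {
    W <- weight_matrix(h, u_obs)
    diag(W) <- 0
    rs <- rowSums(W)
    if (any(rs <= 0)) return(Inf)
    pred <- (W %*% r) / rs
    sum(w_exp * (r - pred)^2)
  }

  crit <- NA_real_
  if (is.null(bandwidth)) {
    scores <- vapply(bandwidth_grid, cv_score, 0)
    if (all(!is.finite(scores)))
      stop("cross-validation failed for every candidate bandwidth")
    bandwidth <- bandwidth_grid[which.min(scores)]
    crit <- min(scores, na.rm = TRUE)
  }
  u_all <- (ages - xl) / (xr - xl)
  m <- drop(weight_matrix(bandwidth, u_all) %*% r)
  out <- data.frame(age = ages, m_grad = m, q_grad = 1 - exp(-m))
  structure(out, bandwidth = bandwidth, criterion = crit,
            method = "beta_kernel",
            class = c("graduated_rates", "data.frame"))
}

#' Graduate every (PI level, period) series of an exposure/death table
#'
#' Each series - including the `Total` pseudo-group, graduated from its own
#' pooled deaths and exposures - is graduated independently.
#'
#' @param tab An [build_table()] result.
#' @param method `"pspline"` (default) or `"beta_kernel"`.
#' @param ... Passed to the graduation function.
#' @return Data frame with columns `age, pi_level, period, m_grad, q_grad,
#'   lambda, criterion` (for the beta kernel, `lambda` holds the
#'   bandwidth).
#' @export
graduate_table <- function(tab, method = c("pspline", "beta_kernel"), ...) {
  method <- match.arg(method)
  fun <- if (method == "pspline") pspline_graduate else beta_kernel_graduate
  out <- list()
  for (p in unique(tab$period)) {
    for (g in unique(tab$pi_level)) {
      s <- tab[tab$period == p & tab$pi_level == g, , drop = FALSE]
      s <- s[order(s$age), ]
      fit <- fun(s$deaths, s$exposure, s$age, ...)
      smooth_par <- if (method == "pspline") attr(fit, "lambda") else
        attr(fit, "bandwidth")
      out[[paste(p, g)]] <- data.frame(
        age = fit$age, pi_level = g, period = p,
        m_grad = fit$m_grad, q_grad = fit$q_grad,
        lambda = smooth_par, criterion = attr(fit, "criterion"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
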