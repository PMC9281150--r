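#' Gompertz-Makeham hazard
#'
#' Force of mortality \eqn{\mu(x) = a + b c^x} at exact age `x` (per year).
#' `a` is the age-independent (Makeham) component, `b` the Gompertz level
#' and `c > 1` the rate of senescent increase.
#'
#' @param age Exact age(s) in years.
#' @param params List with components `a` (>= 0), `b` (>= 0) and `c` (> 1
#'   whenever `b > 0`).
#' @return Hazard value(s), per year.
#' @export
gm_hazard <- function(age, params) {
  check_gm_params(params)
  params$a + params$b * params$c^age
}

# cumulative hazard from age x0 to age x (closed form)
gm_cumhaz <- function(x0, x, params) {
  with(params, {
    g <- if (b > 0) b / log(c) * (c^x - c^x0) else 0
    a * (x - x0) + g
  })
}

check_gm_params <- function(params) {
  stopifnot(is.list(params), all(c("a", "b", "c") %in% names(params)))
  if (params$a < 0 || params$b < 0)
    stop("Gompertz-Makeham 'a' and 'b' must be nonnegative")
  if (params$b > 0 && params$c <= 1)
    stop("Gompertz-Makeham 'c' must exceed 1 when b > 0")
  if (params$a == 0 && params$b == 0)
    stop("hazard is identically zero: set a > 0 or b > 0")
  invisible(params)
}

#' Remaining life expectancy under a Gompertz-Makeham hazard
#'
#' Numerical integration of the survival function
#' \eqn{S(t) = \exp(-\int_0^t \mu(x_0+s)\,ds)} on a fine grid, up to a
#' truncation age. This is the ground truth against which the life-table
#' pipeline's parameter recovery is measured.
#'
#' @param params Gompertz-Makeham parameter list (`a`, `b`, `c`).
#' @param start_age Exact age from which remaining LE is computed.
#' @param max_age Truncation age for the integral (survival beyond it is
#'   negligible for realistic old-age parameters).
#' @param step Integration step in years (trapezoidal rule).
#' @return Remaining life expectancy in years.
#' @export
true_life_expectancy <- function(params, start_age = 65, max_age = 120,
                                 step = 0.01) {
  check_gm_params(params)
  stopifnot(step > 0, max_age > start_age)
  t <- seq(0, max_age - start_age, by = step)
  S <- exp(-gm_cumhaz(start_age, start_age + t, params))
  sum((S[-1] + S[-length(S)]) / 2) * step
}

#' Default per-group Gompertz-Makeham parameters
#'
#' The generator's study conditions: a common Makeham term and senescence
#' rate with group-specific Gompertz levels calibrated to a ~2.5-year
#' Low-to-High gradient in true LE at 65 (about 19.0, 19.8, 20.7 and
#' 21.5 years).
#'
#' @return Named list of parameter lists (`a`, `b`, `c`) per PI group.
#' @export
default_gompertz_params <- function() {
  # Calibrated so the four groups' true LE at 65 are about 19.0, 19.8,
  # 20.7 and 21.5 years: a poorest-to-richest gradient of ~2.5 years,
  # the magnitude observed for male pensioners by pension-income level.
  list(
    "Low"      = list(a = 5e-4, b = 1.212e-5, c = 1.11),
    "Med-Low"  = list(a = 5e-4, b = 1.091e-5, c = 1.11),
    "Med-High" = list(a = 5e-4, b = 9.71e-6,  c = 1.11),
    "High"     = list(a = 5e-4, b = 8.77e-6,  c = 1.11)
  )
}

#' Default record-defect rates
#'
#' Marginal probabilities of each defect class, emulating the published
#' exclusion cascade's first-period percentages of initial records.
#'
#' @return Named numeric vector over the eight exclusion categories.
#' @export
default_contamination_rates <- function() {
  # marginal defect probabilities emulating the published exclusion
  # cascade's first-period percentages of initial records
  c(invalid_birth_date   = 0.0008,
    female               = 0.5079,
    non_retirement       = 0.1939,
    administrative_error = 0.0020,
    deceased_benefit     = 0.0118,
    early_retirement     = 0.1321,
    special_scheme       = 0.0691,
    other_technical      = 0.0013)
}

#' Default per-group pension-amount distributions
#'
#' Lognormal location/scale (EUR/month) per PI group; draws are truncated
#' to the group's cutoff interval so ground-truth labels are exact.
#'
#' @return Named list of `meanlog`/`sdlog` pairs per PI group.
#' @export
default_pension_draw <- function() {
  # lognormal location/scale (EUR/month) per group; draws are truncated to
  # the group's cutoff interval so ground-truth labels are exact
  list(
    "Low"      = list(meanlog = log(520),  sdlog = 0.35),
    "Med-Low"  = list(meanlog = log(1000), sdlog = 0.40),
    "Med-High" = list(meanlog = log(1750), sdlog = 0.25),
    "High"     = list(meanlog = log(2600), sdlog = 0.35)
  )
}

#' Configuration for the synthetic record generator
#'
#' Bundles every knob of [generate_records()]: cohort size, study window,
#' PI-group mix, per-group Gompertz-Makeham mortality, record-defect
#' (contamination) rates, and the per-group pension-amount distributions.
#' Defaults emulate the structure of the Spanish pensioner study population:
#' group weights follow the observed first-period exposure shares,
#' contamination rates follow the published exclusion percentages, and the
#' mortality parameters encode a ~2.5-year Low-to-High LE(65) gradient.
#'
#' @param n_records Number of records to generate (> 0).
#' @param seed Integer seed; identical configs produce byte-identical CSVs.
#' @param period_span Two calendar years `c(start, end)`: the observation
#'   window. Deaths after the window end are emitted as censored.
#' @param group_weights Named proportions over [pi_levels()] (sum to 1).
#' @param gompertz_params Per-group list of `a`, `b`, `c` hazard parameters.
#' @param contamination_rates Named defect proportions (see
#'   `default_contamination_rates()`); all in `[0,1]`, summing to < 1.
#' @param pension_draw Per-group lognormal `meanlog`/`sdlog` (EUR/month),
#'   truncated at draw time to that group's cutoff interval.
#' @param thresholds A [pi_thresholds()] object defining the cutoffs.
#' @param recruitment_years Pension starts are spread uniformly over the
#'   `recruitment_years` calendar years ending at the window end, so the
#'   window contains exposure at all ages 65-101.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_records,
                       seed = 1L,
                       period_span = c(2005L, 2018L),
                       group_weights = c("Low" = 0.1505, "Med-Low" = 0.4801,
                                         "Med-High" = 0.1779, "High" = 0.1915),
                       gompertz_params = default_gompertz_params(),
                       contamination_rates = default_contamination_rates(),
                       pension_draw = default_pension_draw(),
                       thresholds = pi_thresholds(),
                       recruitment_years = 40L) {
  # YAML/JSON configs deliver named lists; coerce to the vector forms
  group_weights <- unlist(group_weights)
  contamination_rates <- unlist(contamination_rates)
  period_span <- unlist(period_span)
  if (length(n_records) != 1 || is.na(n_records) || n_records <= 0)
    stop("n_records must be a positive count")
  if (abs(sum(group_weights) - 1) > 1e-9)
    stop("group_weights must sum to 1")
  if (any(group_weights < 0) || any(contamination_rates < 0) ||
      any(contamination_rates > 1))
    stop("all proportions must lie in [0, 1]")
  if (sum(contamination_rates) >= 1)
    stop("contamination_rates must leave a positive clean fraction")
  stopifnot(length(period_span) == 2, period_span[1] <= period_span[2])
  missing_grp <- setdiff(pi_levels(), names(gompertz_params))
  if (length(missing_grp))
    stop("gompertz_params missing groups: ", paste(missing_grp, collapse = ", "))
  for (g in pi_levels()) check_gm_params(gompertz_params[[g]])
  # fill unspecified defect classes with 0
  rates <- default_contamination_rates() * 0
  rates[names(contamination_rates)] <- contamination_rates
  structure(list(n_records = as.integer(n_records),
                 seed = as.integer(seed),
                 period_span = as.integer(period_span),
                 group_weights = group_weights[pi_levels()],
                 gompertz_params = gompertz_params,
                 contamination_rates = rates,
                 pension_draw = pension_draw,
                 thresholds = thresholds,
                 recruitment_years = as.integer(recruitment_years)),
            class = "sim_config")
}

# Vectorized inverse-CDF sampling of age at death from x0 under a
# Gompertz-Makeham hazard: draw E ~ Exp(1), solve Lambda(x) = Lambda(x0) + E
# for x by monotone interpolation of the closed-form cumulative hazard on a
# fine grid.
sample_gm_death_age <- function(x0, params, grid_step = 0.01, max_age = 130) {
  E <- stats::rexp(length(x0))
  g <- seq(min(55, min(x0)), max_age, by = grid_step)
  Lg <- gm_cumhaz(g[1], g, params)
  L0 <- gm_cumhaz(g[1], x0, params)
  out <- stats::approx(Lg, g, xout = L0 + E, rule = 2)$y
  pmin(out, max_age)
}

#' Generate synthetic pensioner records
#'
#' Draws `n_records` individual records under the mix, mortality and
#' contamination structure of a [sim_config()]. Death ages are sampled by
#' inverting each group's closed-form Gompertz-Makeham cumulative hazard
#' from the age at pension start; deaths beyond the observation window are
#' emitted as censored (empty death date). Contaminated records carry both
#' the data-visible defect (e.g. inconsistent dates for administrative
#' errors) and a ground-truth `defect_class` label for audit.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with one row per record and columns
#'   `person_id, sex, birth_date, pension_start_date, pension_end_date,
#'   death_date, benefit_type, regime, retirement_age_years,
#'   initial_pension_eur_month, defect_class`.
#' @export
generate_records <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_records
  withr_seed <- function() set.seed(config$seed, kind = "Mersenne-Twister",
                                    normal.kind = "Inversion")
  withr_seed()
  groups <- sample(pi_levels(), n, replace = TRUE, prob = config$group_weights)

  # pension start spread over the recruitment window ending at window end
  win_end <- as.Date(sprintf("%d-12-31", config$period_span[2]))
  win_origin <- as.Date(sprintf("%d-01-01",
                                config$period_span[2] - config$recruitment_years))
  span_days <- as.integer(win_end - win_origin)
  pension_start <- win_origin + floor(stats::runif(n) * (span_days + 1))

  # clean records retire at or shortly after 65; ceiling keeps the exact
  # age at pension start at or above the drawn age despite day rounding
  ret_age <- 65 + stats::runif(n) * 0.25
  birth <- pension_start - ceiling(ret_age * DAYS_PER_YEAR)

  # pension amount: truncated lognormal within the group's cutoff interval
  th <- config$thresholds
  cuts <- c(0, th$min_eur, 0.5 * th$max_eur + 0.33 * th$min_eur,
            0.75 * th$max_eur, Inf)
  pension <- numeric(n)
  gi <- match(groups, pi_levels())
  for (g in seq_along(pi_levels())) {
    idx <- which(gi == g)
    if (!length(idx)) next
    pd <- config$pension_draw[[pi_levels()[g]]]
    plo <- stats::plnorm(cuts[g], pd$meanlog, pd$sdlog)
    phi <- stats::plnorm(cuts[g + 1], pd$meanlog, pd$sdlog)
    u <- plo + stats::runif(length(idx)) * (phi - plo)
    pension[idx] <- round(stats::qlnorm(u, pd$meanlog, pd$sdlog), 2)
  }

  # death age by group (exact age at pension start as entry age)
  x0 <- as.numeric(pension_start - birth) / DAYS_PER_YEAR
  death_age <- numeric(n)
  for (g in pi_levels()) {
    idx <- which(groups == g)
    if (!length(idx)) next
    death_age[idx] <- sample_gm_death_age(x0[idx], config$gompertz_params[[g]])
  }
  death <- birth + round(death_age * DAYS_PER_YEAR)
  censored <- death > win_end
  death[censored] <- NA
  pension_end <- death

  rec <- data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    sex = rep("male", n),
    birth_date = birth,
    pension_start_date = pension_start,
    pension_end_date = pension_end,
    death_date = death,
    benefit_type = rep("retirement", n),
    regime = rep("general", n),
    retirement_age_years = round(x0, 4),
    initial_pension_eur_month = pension,
    defect_class = rep("none", n),
    stringsAsFactors = FALSE
  )

  # contamination: at most one defect per record, multinomial assignment
  rates <- config$contamination_rates
  classes <- c(names(rates), "none")
  probs <- c(unname(rates), 1 - sum(rates))
  defect <- sample(classes, n, replace = TRUE, prob = probs)
  rec$defect_class <- defect

  i <- defect == "female"
  rec$sex[i] <- "female"
  i <- which(defect == "non_retirement")
  rec$benefit_type[i] <- sample(c("disability", "survivor", "other"),
                                length(i), replace = TRUE)
  i <- which(defect == "early_retirement")
  if (length(i)) {
    early_age <- 60 + stats::runif(length(i)) * 4.9
    rec$birth_date[i] <- rec$pension_start_date[i] -
      ceiling(early_age * DAYS_PER_YEAR)
    rec$retirement_age_years[i] <-
      round(as.numeric(rec$pension_start_date[i] - rec$birth_date[i]) /
              DAYS_PER_YEAR, 4)
  }
  i <- which(defect == "special_scheme")
  rec$regime[i] <- sample(c("self_employed", "other_special"),
                          length(i), replace = TRUE)
  i <- defect == "invalid_birth_date"
  rec$birth_date[i] <- NA
  i <- defect == "administrative_error"
  rec$pension_start_date[i] <- NA            # missing critical field
  i <- which(defect == "deceased_benefit")
  if (length(i)) {
    # benefit kept in payment after a recorded death
    dd <- rec$death_date[i]
    miss <- is.na(dd)
    dd[miss] <- rec$pension_start_date[i][miss] +
      floor(stats::runif(sum(miss)) * 365)
    rec$death_date[i] <- dd
    rec$pension_end_date[i] <- NA
  }
  i <- defect == "other_technical"
  rec$initial_pension_eur_month[i] <- NA

  attr(rec, "config") <- config
  rec
}

#' Write pensioner records to CSV
#'
#' RFC 4180 CSV, UTF-8, dates in ISO-8601 (`YYYY-MM-DD`), missing dates and
#' amounts as empty strings. Output is byte-identical for identical inputs.
#'
#' @param records Data frame from [generate_records()] or with the same
#'   columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  for (col in c("birth_date", "pension_start_date", "pension_end_date",
                "death_date")) {
    out[[col]] <- ifelse(is.na(out[[col]]),
                         "", format(out[[col]], "%Y-%m-%d"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read pensioner records from CSV
#'
#' Inverse of [write_records()]: parses ISO dates, maps empty strings to
#' missing values.
#'
#' @param path CSV file path.
#' @return Data frame of pensioner records.
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c("birth_date", "pension_start_date", "pension_end_date",
                "death_date")) {
    rec[[col]] <- as_date_or_na(rec[[col]])
  }
  for (col in c("retirement_age_years", "initial_pension_eur_month")) {
    rec[[col]][!nzchar(rec[[col]])] <- NA
    rec[[col]] <- as.numeric(rec[[col]])
  }
  rec
}
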