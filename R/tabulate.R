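#' Define a study period
#'
#' A labelled calendar interval with inclusive endpoints. The standard
#' study windows are `P1` 2005-2010, `P2` 2011-2014 and `P3` 2015-2018.
#'
#' @param label Short label, e.g. `"P1"`.
#' @param start,end Calendar dates (`Date` or ISO-8601 string); `start <=
#'   end`; `end` is inclusive (exposure accrues through the end of that
#'   day).
#' @return An object of class `period_def`.
#' @export
period_def <- function(label, start, end) {
  start <- as_date_or_na(start); end <- as_date_or_na(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("period must have valid start <= end")
  structure(list(label = as.character(label), start = start, end = end),
            class = "period_def")
}

#' Standard study periods
#'
#' @return List of three [period_def()]s: P1 2005-2010, P2 2011-2014,
#'   P3 2015-2018.
#' @export
default_periods <- function() {
  list(period_def("P1", "2005-01-01", "2010-12-31"),
       period_def("P2", "2011-01-01", "2014-12-31"),
       period_def("P3", "2015-01-01", "2018-12-31"))
}

check_periods <- function(periods) {
  if (inherits(periods, "period_def")) periods <- list(periods)
  stopifnot(length(periods) >= 1,
            all(vapply(periods, inherits, TRUE, "period_def")))
  if (length(periods) > 1) {
    ord <- order(vapply(periods, function(p) as.numeric(p$start), 0))
    sorted <- periods[ord]
    for (i in seq_len(length(sorted) - 1)) {
      if (sorted[[i]]$end >= sorted[[i + 1]]$start)
        stop(sprintf("periods overlap: %s and %s",
                     sorted[[i]]$label, sorted[[i + 1]]$label))
    }
  }
  periods
}

# Internal vectorized engine: person-years by completed age for every
# record over one period. Returns list(E = n x n_ages matrix,
# death_age = integer vector (NA if no in-period death)).
exposure_matrix <- function(cohort, period, age_range = c(65L, 101L)) {
  ages <- seq(age_range[1], age_range[2])
  n <- nrow(cohort)
  E <- matrix(0, n, length(ages), dimnames = list(NULL, ages))
  if (n == 0) return(list(E = E, death_age = integer(0), ages = ages))

  birth <- cohort$birth_date
  # observation starts at the latest of pension start, period start and the
  # age_range[1]-th birthday; ends (exclusively) at death, the day after
  # pension end, or the day after the period end
  t0 <- pmax(as.numeric(cohort$pension_start_date),
             as.numeric(period$start),
             as.numeric(add_years(birth, age_range[1])))
  end_excl <- as.numeric(period$end) + 1
  dnum <- as.numeric(cohort$death_date)
  pe <- as.numeric(cohort$pension_end_date) + 1
  t1 <- pmin(ifelse(is.na(dnum), Inf, dnum),
             ifelse(is.na(pe), Inf, pe),
             end_excl)

  bday <- as.numeric(add_years(birth, age_range[1]))
  for (k in seq_along(ages)) {
    bday_next <- if (k == length(ages)) rep(Inf, n) else
      as.numeric(add_years(birth, ages[k] + 1))
    days <- pmax(0, pmin(t1, bday_next) - pmax(t0, bday))
    E[, k] <- days / DAYS_PER_YEAR
    bday <- bday_next
  }

  in_period <- !is.na(cohort$death_date) &
    cohort$death_date >= period$start & cohort$death_date <= period$end
  death_age <- rep(NA_integer_, n)
  if (any(in_period)) {
    da <- age_completed(birth[in_period], cohort$death_date[in_period])
    death_age[in_period] <- pmin(pmax(da, age_range[1]), age_range[2])
  }
  list(E = E, death_age = death_age, ages = ages)
}

#' Person-years of exposure for a single record
#'
#' Exposure accrues from the latest of pension start, period start and the
#' 65th birthday until the earliest of death, pension end and period end,
#' split at birthdays (age last birthday), with day counts divided by
#' 365.25. Ages above 101 are pooled into age 101. A death on an exact
#' birthday contributes zero exposure at the age just attained (half-open
#' `[birthday, next birthday)` intervals) and the death is attributed to
#' that age.
#'
#' @param record One-row data.frame of a cohort record.
#' @param period A [period_def()].
#' @return Data frame with columns `age` and `person_years` (only ages with
#'   positive exposure; empty if the record does not overlap the period).
#' @export
compute_exposure <- function(record, period) {
  stopifnot(nrow(record) == 1, inherits(period, "period_def"))
  em <- exposure_matrix(record, period)
  keep <- em$E[1, ] > 0
  data.frame(age = em$ages[keep], person_years = unname(em$E[1, keep]))
}

#' Tabulate exposures and deaths by age, PI level and period
#'
#' Converts a classified cohort into person-years exposures `E` and death
#' counts `D` by single completed year of age (65-101, older ages pooled
#' into 101), PI level and study period. A `Total` pseudo-group sums over
#' the PI levels.
#'
#' @param cohort Data frame with a `pi_level` column (from
#'   [apply_exclusions()]).
#' @param periods List of non-overlapping [period_def()]s.
#' @param age_range Integer bounds of the tabulation, default `c(65, 101)`.
#' @return A long-format data.frame of class `exposure_death_table` with
#'   columns `age, pi_level, period, exposure, deaths`.
#' @export
build_table <- function(cohort, periods = default_periods(),
                        age_range = c(65L, 101L)) {
  periods <- check_periods(periods)
  stopifnot("pi_level" %in% names(cohort))
  lev <- pi_levels()
  out <- list()
  for (p in periods) {
    em <- exposure_matrix(cohort, p, age_range)
    grp <- factor(as.character(cohort$pi_level), levels = lev)
    if (nrow(em$E) > 0) {
      Eg <- rowsum(em$E, grp)                       # groups x ages
      Eg <- Eg[match(lev, rownames(Eg)), , drop = FALSE]
      Eg[is.na(Eg)] <- 0
      rownames(Eg) <- lev
    } else {
      Eg <- matrix(0, length(lev), length(em$ages))
    }
    Dg <- matrix(0L, length(lev), length(em$ages),
                 dimnames = list(lev, em$ages))
    dead <- !is.na(em$death_age)
    if (any(dead)) {
      tab <- table(factor(as.character(grp[dead]), levels = lev),
                   factor(em$death_age[dead], levels = em$ages))
      Dg <- Dg + as.matrix(tab)
    }
    Eall <- rbind(Eg, Total = colSums(Eg))
    Dall <- rbind(Dg, Total = colSums(Dg))
    out[[p$label]] <- data.frame(
      age = rep(em$ages, each = nrow(Eall)),
      pi_level = rep(rownames(Eall), length(em$ages)),
      period = p$label,
      exposure = as.vector(Eall),
      deaths = as.integer(as.vector(Dall)),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  structure(tab, class = c("exposure_death_table", "data.frame"))
}

#' Group shares of exposures and deaths by period
#'
#' Per-period percentage split of total exposure and deaths across PI
#' levels, rounded to 2 decimals (the layout of the published
#' exposures/deaths table).
#'
#' @param tab An [build_table()] result, or any data.frame with columns
#'   `pi_level, period, exposure, deaths`.
#' @return Data frame with columns `period, pi_level, exposure, deaths,
#'   exposure_share_pct, death_share_pct`.
#' @export
table_shares <- function(tab) {
  d <- tab[tab$pi_level != "Total", , drop = FALSE]
  agg <- stats::aggregate(cbind(exposure, deaths) ~ period + pi_level,
                          data = d, FUN = sum)
  agg$pi_level <- factor(agg$pi_level, levels = pi_levels())
  agg <- agg[order(agg$period, agg$pi_level), ]
  tot_e <- tapply(agg$exposure, agg$period, sum)
  tot_d <- tapply(agg$deaths, agg$period, sum)
  agg$exposure_share_pct <- round(100 * agg$exposure /
                                    tot_e[as.character(agg$period)], 2)
  agg$death_share_pct <- round(100 * agg$deaths /
                                 tot_d[as.character(agg$period)], 2)
  rownames(agg) <- NULL
  agg
}
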