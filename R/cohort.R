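#' Minimum/maximum benefit thresholds for PI classification
#'
#' The legal minimum (`Min`) and maximum (`Max`) monthly benefits in force
#' in the retirement year induce the four pension-income groups:
#' Low `<= Min`; Med-Low in `(Min, 0.5 Max + 0.33 Min]`; Med-High in
#' `(0.5 Max + 0.33 Min, 0.75 Max]`; High `> 0.75 Max`. The defaults are
#' the 2018 values for a single pensioner: Min = 657.60 and
#' Max = 2617.53 EUR/month (14 payments a year). The single-pensioner
#' minimum is used (rather than the dependent-spouse one); both are legal
#' minima and the choice is configurable here.
#'
#' @param min_eur Minimum benefit, EUR/month.
#' @param max_eur Maximum benefit, EUR/month.
#' @param year Retirement year the thresholds are in force for.
#' @return An object of class `pi_thresholds`.
#' @export
pi_thresholds <- function(min_eur = 657.60, max_eur = 2617.53, year = 2018L) {
  if (!(min_eur > 0 && max_eur > min_eur))
    stop("thresholds must satisfy 0 < Min < Max")
  structure(list(min_eur = min_eur, max_eur = max_eur,
                 year = as.integer(year)),
            class = "pi_thresholds")
}

#' Classify a benefit amount into a PI level
#'
#' Applies the cutoff rules literally, with left-open/right-closed
#' boundaries and the coefficient 0.33 as legislated (not 1/3):
#' Low: `B <= Min`; Med-Low: `Min < B <= 0.5 Max + 0.33 Min`;
#' Med-High: `0.5 Max + 0.33 Min < B <= 0.75 Max`; High: `B > 0.75 Max`.
#'
#' @param benefit Initial pension amount(s), EUR/month, `>= 0`.
#' @param thresholds A [pi_thresholds()] object.
#' @return Factor with levels [pi_levels()], same length as `benefit`.
#' @export
classify_pi <- function(benefit, thresholds = pi_thresholds()) {
  stopifnot(inherits(thresholds, "pi_thresholds"))
  if (any(benefit < 0, na.rm = TRUE)) stop("benefit must be nonnegative")
  cut2 <- 0.5 * thresholds$max_eur + 0.33 * thresholds$min_eur
  cut3 <- 0.75 * thresholds$max_eur
  lvl <- ifelse(benefit <= thresholds$min_eur, "Low",
         ifelse(benefit <= cut2, "Med-Low",
         ifelse(benefit <= cut3, "Med-High", "High")))
  factor(lvl, levels = pi_levels())
}

#' Year-indexed benefit thresholds
#'
#' Bundles several [pi_thresholds()] so each pensioner is classified with
#' the Min/Max in force in their retirement year. Years without their own
#' entry use the latest entry at or before them (or the earliest entry for
#' years preceding all entries).
#'
#' @param ... [pi_thresholds()] objects, each with a distinct `year`.
#' @return An object of class `pi_thresholds_table`.
#' @export
pi_thresholds_table <- function(...) {
  entries <- list(...)
  if (length(entries) == 1 && is.list(entries[[1]]) &&
      !inherits(entries[[1]], "pi_thresholds"))
    entries <- entries[[1]]
  stopifnot(length(entries) >= 1,
            all(vapply(entries, inherits, TRUE, "pi_thresholds")))
  years <- vapply(entries, `[[`, 0L, "year")
  if (anyDuplicated(years)) stop("duplicate threshold years")
  structure(entries[order(years)], class = "pi_thresholds_table")
}

# resolve the thresholds entry applying to each retirement year
thresholds_for_year <- function(thresholds, years) {
  if (inherits(thresholds, "pi_thresholds"))
    return(rep(list(thresholds), length(years)))
  stopifnot(inherits(thresholds, "pi_thresholds_table"))
  tyears <- vapply(thresholds, `[[`, 0L, "year")
  idx <- findInterval(years, tyears)
  idx[idx == 0] <- 1
  thresholds[idx]
}

# classify benefits with per-record thresholds (vectorized over the small
# number of distinct threshold years)
classify_pi_by_year <- function(benefit, years, thresholds) {
  if (inherits(thresholds, "pi_thresholds"))
    return(classify_pi(benefit, thresholds))
  entry <- thresholds_for_year(thresholds, years)
  key <- vapply(entry, `[[`, 0L, "year")
  out <- factor(rep(NA_character_, length(benefit)), levels = pi_levels())
  for (y in unique(key)) {
    i <- key == y
    out[i] <- classify_pi(benefit[i], entry[[which(key == y)[1]]])
  }
  out
}

exclusion_categories <- function() {
  c("invalid_birth_date", "female", "non_retirement", "administrative_error",
    "deceased_benefit", "early_retirement", "special_scheme",
    "other_technical")
}

#' Build a filter report from category counts
#'
#' An auditable record of the exclusion cascade: ordered per-category
#' counts, the initial and final cohort sizes, and percentages of the
#' initial count (2 decimals). Counts must conserve:
#' `initial = final + sum(excluded)`.
#'
#' @param initial_count Number of records entering the cascade.
#' @param excluded Named integer vector of per-category exclusion counts;
#'   names must be a subset of the fixed category order (missing categories
#'   count 0).
#' @return An object of class `filter_report`: a data.frame of rows
#'   (category, excluded, pct) with attributes `initial`, `final`,
#'   `retention_pct`.
#' @export
filter_report <- function(initial_count, excluded) {
  cats <- exclusion_categories()
  counts <- stats::setNames(rep(0L, length(cats)), cats)
  if (length(excluded)) {
    unknown <- setdiff(names(excluded), cats)
    if (length(unknown))
      stop("unknown exclusion categories: ", paste(unknown, collapse = ", "))
    counts[names(excluded)] <- as.integer(excluded)
  }
  final <- initial_count - sum(counts)
  if (final < 0) stop("excluded counts exceed the initial count")
  rep <- data.frame(category = cats,
                    excluded = unname(counts),
                    pct = round(100 * unname(counts) / initial_count, 2),
                    stringsAsFactors = FALSE)
  structure(rep,
            initial = initial_count,
            final = final,
            retention_pct = round(100 * final / initial_count, 2),
            class = c("filter_report", "data.frame"))
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Exclusion cascade: %s initial records\n",
              format(attr(x, "initial"), big.mark = ",")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  - %-22s %12s  (%.2f%%)\n", x$category[i],
                format(x$excluded[i], big.mark = ","), x$pct[i]))
  }
  cat(sprintf("  = final cohort         %12s  (%.2f%%)\n",
              format(attr(x, "final"), big.mark = ","),
              attr(x, "retention_pct")))
  invisible(x)
}

#' Retention percentage of a filter report
#'
#' @param report A [filter_report()].
#' @return Final cohort size as a percentage of the initial count,
#'   rounded to 2 decimals.
#' @export
retention_pct <- function(report) {
  stopifnot(inherits(report, "filter_report"))
  attr(report, "retention_pct")
}

#' Apply the exclusion cascade and PI classification
#'
#' Retains male, general-regime retirement pensioners with valid dates who
#' retired at age 65 or later, excluding every other record under a fixed
#' category precedence (invalid birth date, female, non-retirement benefit,
#' administrative error, deceased-pensioner benefit, early retirement,
#' special scheme, other technical). A record failing several rules is
#' counted once, in the first matching category, so the report conserves
#' counts. Unparseable or inconsistent rows are counted as administrative
#' errors, never silently dropped. Retained records are classified into PI
#' levels from their initial pension amount.
#'
#' @param records Data frame of pensioner records (see [generate_records()]
#'   for the schema); date columns may be `Date` or ISO-8601 strings.
#' @param thresholds A [pi_thresholds()] (applied to every record) or a
#'   [pi_thresholds_table()] (each record classified with the thresholds
#'   in force in its retirement year).
#' @param reference_period Optional [period_def()]; when given, only records
#'   whose pension overlaps the period enter the cascade (the per-period
#'   initial count of an administrative extract).
#' @return List with elements `cohort` (retained records plus a `pi_level`
#'   column) and `report` (a [filter_report()]).
#' @export
apply_exclusions <- function(records, thresholds = pi_thresholds(),
                             reference_period = NULL) {
  rec <- records
  for (col in c("birth_date", "pension_start_date", "pension_end_date",
                "death_date")) {
    rec[[col]] <- as_date_or_na(rec[[col]])
  }
  if (!is.null(reference_period)) {
    stopifnot(inherits(reference_period, "period_def"))
    starts_ok <- is.na(rec$pension_start_date) |
      rec$pension_start_date <= reference_period$end
    ends <- rec$death_date
    ends[is.na(ends)] <- rec$pension_end_date[is.na(ends)]
    in_force <- is.na(ends) | ends >= reference_period$start
    rec <- rec[starts_ok & in_force, , drop = FALSE]
  }
  n <- nrow(rec)
  if (n == 0) {
    return(list(cohort = cbind(rec, pi_level = factor(character(0),
                                                      levels = pi_levels())),
                report = filter_report(0L, integer(0))))
  }

  isTRUEv <- function(x) !is.na(x) & x
  masks <- list(
    invalid_birth_date = is.na(rec$birth_date),
    female = is.na(rec$sex) | rec$sex != "male",
    non_retirement = rec$benefit_type %in% c("disability", "survivor",
                                             "other"),
    administrative_error = is.na(rec$pension_start_date) |
      isTRUEv(rec$pension_start_date <= rec$birth_date) |
      isTRUEv(rec$death_date < rec$pension_start_date),
    deceased_benefit = !is.na(rec$death_date) &
      (is.na(rec$pension_end_date) |
         isTRUEv(rec$pension_end_date > rec$death_date)),
    early_retirement = isTRUEv(rec$benefit_type == "early_retirement") |
      isTRUEv(rec$retirement_age_years < 65),
    special_scheme = is.na(rec$regime) | rec$regime != "general",
    other_technical = is.na(rec$initial_pension_eur_month) |
      isTRUEv(rec$initial_pension_eur_month < 0) |
      is.na(rec$retirement_age_years)
  )
  counts <- integer(0)
  already <- rep(FALSE, n)
  for (cat in exclusion_categories()) {
    hit <- masks[[cat]] & !already
    counts[cat] <- sum(hit)
    already <- already | hit
  }
  cohort <- rec[!already, , drop = FALSE]
  ret_year <- as.integer(format(cohort$pension_start_date, "%Y"))
  cohort$pi_level <- classify_pi_by_year(cohort$initial_pension_eur_month,
                                         ret_year, thresholds)
  rownames(cohort) <- NULL
  list(cohort = cohort, report = filter_report(n, counts))
}
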