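# Internal calendar helpers. All exposure arithmetic is done on day counts
# with a fixed 365.25-day year; these helpers only construct anniversary
# dates.

DAYS_PER_YEAR <- 365.25

# Gregorian (y, m, d) -> days since 1970-01-01, fully vectorized integer
# arithmetic (standard Julian-day-number formula, JDN of the epoch is
# 2440588). Used instead of string parsing for speed on large cohorts.
ymd_to_days <- function(y, m, d) {
  a <- (14 - m) %/% 12
  y2 <- y + 4800 - a
  m2 <- m + 12 * a - 3
  d + (153 * m2 + 2) %/% 5 + 365 * y2 + y2 %/% 4 - y2 %/% 100 +
    y2 %/% 400 - 32045 - 2440588
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

# Add k whole years to a vector of Dates. A Feb 29 anniversary in a
# non-leap year rolls back to Feb 28 (the person has completed the year by
# then, so the earlier date is the conservative convention).
add_years <- function(dates, k) {
  lt <- as.POSIXlt(dates)
  y <- lt$year + 1900L + as.integer(k)
  m <- lt$mon + 1L
  d <- lt$mday
  fix <- !is.na(d) & m == 2L & d == 29L & !is_leap(y)
  d[fix] <- 28L
  as.Date(ymd_to_days(y, m, d), origin = "1970-01-01")
}

# Completed years of age at `date` for a person born on `birth`
# (age last birthday). A date falling exactly on the anniversary counts the
# new age.
age_completed <- function(birth, date) {
  y <- as.integer(format(date, "%Y")) - as.integer(format(birth, "%Y"))
  # lexicographic mm-dd comparison decides whether the birthday has passed
  before_bday <- format(date, "%m-%d") < format(birth, "%m-%d")
  y - as.integer(before_bday)
}

as_date_or_na <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  as.Date(x, format = "%Y-%m-%d")
}
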