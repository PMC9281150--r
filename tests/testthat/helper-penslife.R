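# Shared fixtures and independent oracles for the test suite.

# A clean (defect-free), all-male, retire-at-65 configuration.
clean_config <- function(n, seed = 1L,
                         group_weights = c("Low" = 0.25, "Med-Low" = 0.25,
                                           "Med-High" = 0.25, "High" = 0.25),
                         ...) {
  sim_config(n, seed = seed, group_weights = group_weights,
             contamination_rates = c(female = 0), ...)
}

# One-group configuration (all mass on `group`).
one_group_config <- function(n, group = "Low", seed = 1L, ...) {
  w <- c("Low" = 0, "Med-Low" = 0, "Med-High" = 0, "High" = 0)
  w[group] <- 1
  clean_config(n, seed = seed, group_weights = w, ...)
}

# Independent life-expectancy oracle: explicit survivorship loop over a
# discrete schedule with mid-year deaths and an open final age with
# person-years a_last = min(1 / m_last, 1). Deliberately written as a
# scalar loop, not sharing any code path with build_life_table().
oracle_le <- function(q, m_last) {
  n <- length(q)
  l <- 1
  total <- 0
  for (i in seq_len(n - 1)) {
    d <- l * q[i]
    total <- total + (l - d) + 0.5 * d
    l <- l - d
  }
  a_last <- if (is.finite(m_last) && m_last > 0) min(1 / m_last, 1) else 1
  total + l * a_last
}

# Single synthetic cohort record as a one-row cohort data.frame.
one_record <- function(birth, start, death = NA, pension_end = NA,
                       pi_level = "Low") {
  data.frame(
    person_id = "X1", sex = "male",
    birth_date = as.Date(birth),
    pension_start_date = as.Date(start),
    pension_end_date = as.Date(if (is.na(pension_end)) NA else pension_end),
    death_date = as.Date(if (is.na(death)) NA else death),
    benefit_type = "retirement", regime = "general",
    retirement_age_years = as.numeric(as.Date(start) - as.Date(birth)) /
      365.25,
    initial_pension_eur_month = 600,
    pi_level = factor(pi_level, levels = pi_levels()),
    stringsAsFactors = FALSE
  )
}
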