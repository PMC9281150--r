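# End-to-end orchestration: simulate (optional) -> filter -> tabulate ->
# graduate -> life tables -> inequality summaries, with every stage result
# written to CSV so any stage can be re-run from the previous stage's file.

parse_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$input) && is.null(config$simulate))
    stop("config needs either an 'input' CSV path or a 'simulate' block")
  if (!is.null(config$input) && !file.exists(config$input))
    stop("input file not found: ", config$input)
  config
}

config_periods <- function(config) {
  if (is.null(config$periods)) return(default_periods())
  check_periods(lapply(config$periods, function(p)
    period_def(p$label, p$start, p$end)))
}

config_thresholds <- function(config) {
  th <- config$thresholds
  if (is.null(th)) return(pi_thresholds())
  if (!is.null(th$min_eur))
    return(pi_thresholds(min_eur = th$min_eur, max_eur = th$max_eur,
                         year = if (is.null(th$year)) 2018L else th$year))
  # year-keyed map: {year: {min_eur: , max_eur: }}
  pi_thresholds_table(lapply(names(th), function(y)
    pi_thresholds(th[[y]]$min_eur, th[[y]]$max_eur, as.integer(y))))
}

#' Run the full mortality-inequality pipeline
#'
#' Executes every stage in order and writes all intermediate and final
#' tables under `out_dir`: the (optionally simulated) records, filter
#' report, exposure/death table, graduated rates, life tables, LE summary
#' with CIs, pairwise LE difference tests, relative-mortality and
#' mortality-improvement tables, LE gap trend, plots of LE by PI level,
#' and a machine-readable `summary.json`. A `MANIFEST.txt` lists the
#' outputs; if a stage fails, the manifest records the partial state and
#' the error is re-raised with the stage name.
#'
#' @param config A list or a YAML file path. Keys: `seed`; either
#'   `simulate` (arguments of [sim_config()]) or `input` (records CSV
#'   path); optional `thresholds` (`min_eur`, `max_eur`), `periods` (list
#'   of `label`/`start`/`end`), `graduation` (`method`, plus arguments of
#'   the graduation function).
#' @param out_dir Output directory, created if needed.
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list with the main stage results (`report`, `tab`,
#'   `grad`, `le`, `differences`, `rm`, `improvements`, `trend`,
#'   `summary`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- parse_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  note <- function(f) manifest <<- c(manifest, f)
  write_manifest <- function(status) {
    writeLines(c(paste("status:", status), manifest),
               file.path(out_dir, "MANIFEST.txt"))
  }
  stage <- "setup"
  result <- tryCatch({
    periods <- config_periods(config)
    thresholds <- config_thresholds(config)

    stage <- "simulate"
    if (!is.null(config$simulate)) {
      message("[simulate] generating ", config$simulate$n_records,
              " records")
      sim_args <- config$simulate
      sim_args$seed <- config$seed
      # the generator truncates pension draws against one cutoff set; with
      # a year table, use the most recent entry
      sim_args$thresholds <- if (inherits(thresholds, "pi_thresholds"))
        thresholds else thresholds[[length(thresholds)]]
      cfg <- do.call(sim_config, sim_args)
      records <- generate_records(cfg)
      write_records(records, file.path(out_dir, "records.csv"))
      note("records.csv")
    } else {
      message("[simulate] skipped; reading ", config$input)
      records <- read_records(config$input)
    }

    stage <- "filter"
    flt <- apply_exclusions(records, thresholds)
    message(sprintf("[filter] %d of %d records retained",
                    attr(flt$report, "final"), attr(flt$report, "initial")))
    utils::write.csv(as.data.frame(flt$report),
                     file.path(out_dir, "filter_report.csv"),
                     row.names = FALSE)
    note("filter_report.csv")
    cohort_out <- flt$cohort
    for (col in c("birth_date", "pension_start_date", "pension_end_date",
                  "death_date"))
      cohort_out[[col]] <- ifelse(is.na(cohort_out[[col]]), "",
                                  format(cohort_out[[col]], "%Y-%m-%d"))
    utils::write.csv(cohort_out, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    note("cohort.csv")

    stage <- "tabulate"
    tab <- build_table(flt$cohort, periods)
    utils::write.csv(tab, file.path(out_dir, "exposure_deaths.csv"),
                     row.names = FALSE)
    note("exposure_deaths.csv")
    message("[tabulate] ", nrow(tab), " cells over ",
            length(periods), " periods")

    stage <- "graduate"
    grad_args <- config$graduation
    method <- if (is.null(grad_args$method)) "pspline" else grad_args$method
    grad_args$method <- NULL
    grad <- do.call(graduate_table, c(list(tab = tab, method = method),
                                      grad_args))
    utils::write.csv(grad, file.path(out_dir, "graduated.csv"),
                     row.names = FALSE)
    note("graduated.csv")
    message("[graduate] method = ", method)

    stage <- "lifetable"
    le_rows <- list(); lt_rows <- list()
    for (p in vapply(periods, `[[`, "", "label")) {
      for (g in c(pi_levels(), "Total")) {
        gg <- grad[grad$period == p & grad$pi_level == g, ]
        gg <- gg[order(gg$age), ]
        tg <- tab[tab$period == p & tab$pi_level == g, ]
        tg <- tg[order(tg$age), ]
        ls <- le_summary(gg$q_grad, gg$m_grad, tg$exposure, ages = gg$age)
        le_rows[[paste(p, g)]] <- cbind(pi_level = g, period = p, ls)
        lt <- build_life_table(gg$q_grad, gg$age, mx = gg$m_grad)
        lt_rows[[paste(p, g)]] <- cbind(pi_level = g, period = p,
                                        as.data.frame(lt))
      }
    }
    le <- do.call(rbind, le_rows); rownames(le) <- NULL
    lts <- do.call(rbind, lt_rows); rownames(lts) <- NULL
    utils::write.csv(lts, file.path(out_dir, "life_tables.csv"),
                     row.names = FALSE)
    utils::write.csv(le, file.path(out_dir, "le_summary.csv"),
                     row.names = FALSE)
    note("life_tables.csv"); note("le_summary.csv")
    message("[lifetable] LE summaries for ", nrow(le) , " group-period-ages")

    stage <- "differences"
    pairs <- list(c("High", "Med-High"), c("High", "Med-Low"),
                  c("High", "Low"), c("Med-High", "Med-Low"),
                  c("Med-High", "Low"), c("Med-Low", "Low"))
    diff_rows <- list()
    for (p in unique(le$period)) {
      for (a in unique(le$age)) {
        for (pr in pairs) {
          sa <- le[le$period == p & le$age == a & le$pi_level == pr[1], ]
          sb <- le[le$period == p & le$age == a & le$pi_level == pr[2], ]
          d <- compare_le(sa, sb, p, p)
          diff_rows[[paste(p, a, pr[1], pr[2])]] <- data.frame(
            period = p, age = a, group_a = pr[1], group_b = pr[2],
            dle = d$dle, se = d$se, z = d$z,
            significance = d$significance, stringsAsFactors = FALSE)
        }
      }
    }
    differences <- do.call(rbind, diff_rows); rownames(differences) <- NULL
    utils::write.csv(differences, file.path(out_dir, "le_differences.csv"),
                     row.names = FALSE)
    note("le_differences.csv")

    stage <- "inequality"
    rm_tab <- relative_mortality(grad, tab)
    utils::write.csv(rm_tab, file.path(out_dir, "relative_mortality.csv"),
                     row.names = FALSE)
    note("relative_mortality.csv")
    difs <- dif_low_high(rm_tab)
    utils::write.csv(difs, file.path(out_dir, "rm_dif_low_high.csv"),
                     row.names = FALSE)
    note("rm_dif_low_high.csv")
    imp_rows <- list()
    plabels <- vapply(periods, `[[`, "", "label")
    if (length(plabels) >= 2) {
      combos <- utils::combn(seq_along(plabels), 2, simplify = FALSE)
      for (cb in combos) {
        pe <- plabels[cb[1]]; pl <- plabels[cb[2]]
        imp <- mortality_improvement(
          grad[grad$period == pe, ], grad[grad$period == pl, ],
          tab, pe, pl)
        imp_rows[[paste(pe, pl)]] <- cbind(period_pair = paste0(pe, "-", pl),
                                           imp)
      }
    }
    improvements <- if (length(imp_rows)) do.call(rbind, imp_rows) else NULL
    if (!is.null(improvements)) {
      rownames(improvements) <- NULL
      utils::write.csv(improvements, file.path(out_dir, "improvements.csv"),
                       row.names = FALSE)
      note("improvements.csv")
    }
    le65 <- le[le$age == 65, c("period", "pi_level", "le")]
    trend <- if (length(plabels) >= 2)
      gap_trend(le65[le65$pi_level != "Total", ]) else NULL
    if (!is.null(trend)) {
      utils::write.csv(cbind(trend$gaps, slope = trend$slope),
                       file.path(out_dir, "gap_trend.csv"),
                       row.names = FALSE)
      note("gap_trend.csv")
    }

    stage <- "figures"
    plot_le_by_group(le, 65, file.path(out_dir, "le65_by_group.pdf"))
    plot_le_by_group(le, 75, file.path(out_dir, "le75_by_group.pdf"))
    note("le65_by_group.pdf"); note("le75_by_group.pdf")
    if (!is.null(trend)) {
      plot_gap_trend(trend, file.path(out_dir, "le65_gap_trend.pdf"))
      note("le65_gap_trend.pdf")
    }

    stage <- "summary"
    summary <- list(
      seed = config$seed,
      n_initial = attr(flt$report, "initial"),
      n_cohort = attr(flt$report, "final"),
      retention_pct = retention_pct(flt$report),
      le65 = stats::setNames(
        lapply(split(le65, le65$period), function(d)
          as.list(stats::setNames(round(d$le, 4), d$pi_level))),
        unique(le65$period)),
      le65_gap_low_high = if (!is.null(trend))
        stats::setNames(as.list(round(trend$gaps$gap, 4)),
                        trend$gaps$period) else NULL,
      gap_slope_per_period = if (!is.null(trend))
        round(trend$slope, 4) else NULL
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("summary.json")
    write_manifest("complete")
    list(report = flt$report, tab = tab, grad = grad, le = le,
         differences = differences, rm = rm_tab,
         improvements = improvements, trend = trend, summary = summary)
  }, error = function(e) {
    write_manifest(paste0("incomplete (failed at stage '", stage, "')"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

plot_le_by_group <- function(le, at_age, path) {
  d <- le[le$age == at_age & le$pi_level != "Total", ]
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  periods <- sort(unique(d$period))
  groups <- pi_levels()
  mat <- sapply(groups, function(g)
    d$le[match(paste(periods, g), paste(d$period, d$pi_level))])
  graphics::matplot(seq_along(periods), mat, type = "b", pch = 19,
                    lty = 1, col = seq_along(groups),
                    xaxt = "n", xlab = "Period",
                    ylab = sprintf("LE at age %d (years)", at_age),
                    main = sprintf("Life expectancy at %d by PI level",
                                   at_age))
  graphics::axis(1, at = seq_along(periods), labels = periods)
  graphics::legend("topleft", legend = groups, col = seq_along(groups),
                   pch = 19, lty = 1, bty = "n")
  invisible(path)
}

plot_gap_trend <- function(trend, path) {
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  idx <- seq_len(nrow(trend$gaps))
  graphics::plot(idx, trend$gaps$gap, type = "b", pch = 19, xaxt = "n",
                 xlab = "Period", ylab = "LE(65) gap High - Low (years)",
                 main = sprintf("Low-High LE gap (trend %.2f y/period)",
                                trend$slope))
  graphics::axis(1, at = idx, labels = trend$gaps$period)
  graphics::abline(stats::lm(trend$gaps$gap ~ idx), lty = 2)
  invisible(path)
}
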