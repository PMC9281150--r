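# Inequality summaries: relative-mortality ratios by 5-year age group,
# Low-High gaps, mortality improvements between periods, and LE-gap trends.

#' Five-year age-group scheme
#'
#' The reporting bins 65-69, 70-74, 75-79, 80-84 and 85+ (85+ pools ages
#' 85-101), plus a `Total` bin covering the whole range.
#'
#' @param age_range Integer bounds, default `c(65, 101)`.
#' @return Object of class `age_group_scheme`: list with `labels` and a
#'   `bin(ages)` function mapping single ages to bin labels.
#' @export
age_group_scheme <- function(age_range = c(65L, 101L)) {
  breaks <- c(65, 70, 75, 80, 85, age_range[2] + 1)
  labels <- c("65-69", "70-74", "75-79", "80-84", "85+")
  structure(list(
    labels = labels,
    breaks = breaks,
    bin = function(ages) {
      as.character(cut(ages, breaks = breaks, labels = labels,
                       right = FALSE, include.lowest = TRUE))
    }
  ), class = "age_group_scheme")
}

# exposure-weighted bin rate: q_h = sum(E_x q_x) / sum(E_x) within the bin
bin_rates <- function(q, E, ages, scheme) {
  bins <- scheme$bin(ages)
  out <- vapply(scheme$labels, function(b) {
    i <- bins == b
    Etot <- sum(E[i])
    if (Etot <= 0) return(NA_real_)
    sum(E[i] * q[i]) / Etot
  }, 0)
  Etot_all <- sum(E)
  c(out, Total = if (Etot_all > 0) sum(E * q) / Etot_all else NA_real_)
}

#' Relative mortality ratios by age group and PI level
#'
#' For each 5-year age group `h`, PI level `m` and period, the ratio of the
#' group's exposure-weighted graduated death rate to the whole cohort's
#' rate for the same ages: `RM = q_h^m / q_h^T`. A ratio of 1.00 means the
#' group dies at the overall rate; below 1.00, slower; above, faster. The
#' `Total` age-group row pools all ages 65-101.
#'
#' The denominator `q_h^T` comes either from the pooled-data graduation of
#' the `Total` series (`total = "pooled"`, the default) or from
#' exposure-weighting the group rates (`total = "weighted"`, under which
#' the exposure-weighted mean RM across groups is exactly 1).
#'
#' @param grad Graduated rates data.frame (`age, pi_level, period, q_grad`;
#'   from [graduate_table()]), including a `Total` series when
#'   `total = "pooled"`.
#' @param tab Exposure/death table ([build_table()]) supplying the weights.
#' @param scheme An [age_group_scheme()].
#' @param total Denominator convention, `"pooled"` or `"weighted"`.
#' @return Data frame of class `relative_mortality_table` with columns
#'   `period, age_group, pi_level, rm`.
#' @export
relative_mortality <- function(grad, tab, scheme = age_group_scheme(),
                               total = c("pooled", "weighted")) {
  total <- match.arg(total)
  out <- list()
  for (p in unique(grad$period)) {
    gp <- grad[grad$period == p, ]
    tp <- tab[tab$period == p, ]
    rates <- list()
    for (g in pi_levels()) {
      gg <- gp[gp$pi_level == g, ]; gg <- gg[order(gg$age), ]
      tg <- tp[tp$pi_level == g, ]; tg <- tg[order(tg$age), ]
      if (!nrow(gg)) stop("no graduated rates for group ", g,
                          " in period ", p)
      if (any(tapply(tg$exposure, scheme$bin(tg$age), sum) <= 0))
        stop("empty bin exposure for group ", g, " in period ", p)
      rates[[g]] <- bin_rates(gg$q_grad, tg$exposure, gg$age, scheme)
    }
    if (total == "pooled") {
      gt <- gp[gp$pi_level == "Total", ]; gt <- gt[order(gt$age), ]
      if (!nrow(gt))
        stop("total = \"pooled\" needs a graduated Total series")
      tt <- tp[tp$pi_level == "Total", ]; tt <- tt[order(tt$age), ]
      denom <- bin_rates(gt$q_grad, tt$exposure, gt$age, scheme)
    } else {
      # exposure-weighted pooled rate across groups, bin by bin
      Eg <- sapply(pi_levels(), function(g) {
        tg <- tp[tp$pi_level == g, ]; tg <- tg[order(tg$age), ]
        c(tapply(tg$exposure, factor(scheme$bin(tg$age),
                                     levels = scheme$labels), sum),
          Total = sum(tg$exposure))
      })
      Rg <- sapply(pi_levels(), function(g) rates[[g]])
      denom <- rowSums(Eg * Rg) / rowSums(Eg)
    }
    for (g in pi_levels()) {
      out[[paste(p, g)]] <- data.frame(
        period = p,
        age_group = names(rates[[g]]),
        pi_level = g,
        rm = unname(rates[[g]] / denom),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("relative_mortality_table", "data.frame"))
}

#' Low-High gap in relative mortality
#'
#' `Dif = RM_Low - RM_High` per age group and period.
#'
#' @param rm_table A [relative_mortality()] result.
#' @return Data frame with columns `period, age_group, dif_low_high`.
#' @export
dif_low_high <- function(rm_table) {
  lo <- rm_table[rm_table$pi_level == "Low", ]
  hi <- rm_table[rm_table$pi_level == "High", ]
  m <- merge(lo[, c("period", "age_group", "rm")],
             hi[, c("period", "age_group", "rm")],
             by = c("period", "age_group"), suffixes = c("_low", "_high"))
  m$dif_low_high <- m$rm_low - m$rm_high
  m[order(m$period, m$age_group), c("period", "age_group", "dif_low_high")]
}

#' Mortality improvement between two periods
#'
#' Percentage reduction in the exposure-weighted graduated death rates from
#' an earlier to a later period, by age group and PI level:
#' `100 * (1 - sum(w q_later) / sum(w q_earlier))`. Positive values mean
#' improvement; negative values mean deterioration. The weights `w_x` are
#' the exposures of the earlier period by default (a fixed, Laspeyres-style
#' standard), switchable to the later period's.
#'
#' @param grad_earlier,grad_later Graduated rates for one period each
#'   (columns `age, pi_level, q_grad`) on the same age range.
#' @param tab Exposure/death table containing both periods.
#' @param period_earlier,period_later Period labels inside `tab`.
#' @param scheme An [age_group_scheme()].
#' @param weight_period Which period's exposures weight the rates.
#' @return Data frame with columns `age_group, pi_level,
#'   improvement_pct`.
#' @export
mortality_improvement <- function(grad_earlier, grad_later, tab,
                                  period_earlier, period_later,
                                  scheme = age_group_scheme(),
                                  weight_period = c("earlier", "later")) {
  weight_period <- match.arg(weight_period)
  wp <- if (weight_period == "earlier") period_earlier else period_later
  groups <- unique(grad_earlier$pi_level)
  out <- list()
  for (g in groups) {
    ge <- grad_earlier[grad_earlier$pi_level == g, ]
    gl <- grad_later[grad_later$pi_level == g, ]
    ge <- ge[order(ge$age), ]; gl <- gl[order(gl$age), ]
    if (!identical(ge$age, gl$age))
      stop("periods graduated on different age ranges for group ", g)
    tw <- tab[tab$period == wp & tab$pi_level == g, ]
    tw <- tw[order(tw$age), ]
    bins <- c(scheme$labels, "Total")
    binv <- scheme$bin(ge$age)
    for (b in bins) {
      i <- if (b == "Total") rep(TRUE, nrow(ge)) else binv == b
      w <- tw$exposure[i]
      num_e <- sum(w * ge$q_grad[i]); num_l <- sum(w * gl$q_grad[i])
      if (num_e <= 0)
        stop("zero weighted rate in the earlier period (group ", g,
             ", bin ", b, ")")
      out[[paste(g, b)]] <- data.frame(
        age_group = b, pi_level = g,
        improvement_pct = 100 * (1 - num_l / num_e),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Low-High LE gaps by period and their linear trend
#'
#' Gaps are `LE_High - LE_Low` (positive when the richest group lives
#' longer); the trend is the ordinary least-squares slope of the gap on the
#' period index (1, 2, ...), in years per period step.
#'
#' @param le_by_group Data frame with columns `period, pi_level, le`
#'   containing at least the `Low` and `High` rows for two or more periods;
#'   alternatively a data.frame with columns `period, gap`.
#' @return List with `gaps` (data.frame `period, gap`) and `slope`.
#' @export
gap_trend <- function(le_by_group) {
  if (all(c("period", "gap") %in% names(le_by_group))) {
    gaps <- le_by_group[, c("period", "gap")]
  } else {
    stopifnot(all(c("period", "pi_level", "le") %in% names(le_by_group)))
    lo <- le_by_group[le_by_group$pi_level == "Low", ]
    hi <- le_by_group[le_by_group$pi_level == "High", ]
    m <- merge(lo[, c("period", "le")], hi[, c("period", "le")],
               by = "period", suffixes = c("_low", "_high"))
    gaps <- data.frame(period = m$period, gap = m$le_high - m$le_low)
  }
  gaps <- gaps[order(gaps$period), , drop = FALSE]
  if (nrow(gaps) < 2) stop("need at least 2 periods for a trend")
  idx <- seq_len(nrow(gaps))
  slope <- unname(stats::coef(stats::lm(gaps$gap ~ idx))[2])
  list(gaps = gaps, slope = slope)
}
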