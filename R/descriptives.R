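#' Quarterly mean with a 95% confidence interval for one calendar year
#'
#' The point estimate is the arithmetic mean of the four quarterly values of
#' `measure` in `year`. Quarterly counts carry strong quarter-of-year
#' seasonality, so the default interval first removes estimated
#' quarter-of-year effects before computing the dispersion: quarter dummies
#' are regressed on the full available series (or a supplied reference
#' window), the year's four values are adjusted by the centred seasonal
#' offsets, and the interval is `mean +/- t(0.975, 3) * sd(adjusted) / 2`.
#' A plain t-interval on the raw four values is available via
#' `scheme = "raw"`. The scheme used is recorded in the result, and a
#' degenerate (constant) year yields a zero-width interval under either
#' scheme.
#'
#' @param panel single-stratum `waitlist_panel`.
#' @param measure one of `"pending"`, `"removals"`, `"additions"`.
#' @param year calendar year; all four quarters must be present.
#' @param scheme `"seasonal"` (default) or `"raw"`.
#' @param level confidence level.
#' @param season_window optional integer years used to estimate the seasonal
#'   offsets (default: every complete year in the panel).
#' @return a `period_summary` list: `year`, `mean`, `lower`, `upper`,
#'   `n_quarters`, `scheme`, `measure`.
#' @export
quarterly_mean_ci <- function(panel, measure = c("pending", "removals", "additions"),
                              year, scheme = c("seasonal", "raw"),
                              level = 0.95, season_window = NULL) {
  measure <- match.arg(measure)
  scheme <- match.arg(scheme)
  s <- panel_series(panel)
  v <- s[[measure]]
  yr <- qcode_year(s$code)
  qoy <- qcode_quarter(s$code)
  sel <- which(yr == year)
  if (length(sel) != 4) {
    stop("year ", year, " has ", length(sel),
         " quarters in the panel; all four are required")
  }
  x <- v[sel]
  m <- mean(x)
  if (scheme == "seasonal") {
    ref <- if (is.null(season_window)) {
      complete <- as.numeric(names(which(table(yr) == 4)))
      which(yr %in% complete)
    } else {
      which(yr %in% season_window)
    }
    if (length(ref) < 8) {
      stop("need at least two complete years to estimate seasonal offsets")
    }
    # quarter-of-year effects from a dummy regression, after removing a
    # linear trend so that secular growth is not absorbed into the offsets
    fit <- stats::lm(v[ref] ~ seq_along(ref) + factor(qoy[ref]))
    co <- stats::coef(fit)
    eff <- c(0, co[grep("^factor", names(co))])
    eff <- eff - mean(eff)                       # centred seasonal offsets
    adj <- x - eff[qoy[sel]]
  } else {
    adj <- x
  }
  sdev <- stats::sd(adj)
  half <- stats::qt(1 - (1 - level) / 2, df = length(x) - 1) *
    sdev / sqrt(length(x))
  out <- list(year = year, mean = m, lower = m - half, upper = m + half,
              n_quarters = length(x), scheme = scheme, measure = measure)
  class(out) <- "period_summary"
  out
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("%s, %d: mean %.1f (95%% CI %.1f; %.1f) over %d quarters [%s scheme]\n",
              x$measure, x$year, x$mean, x$lower, x$upper, x$n_quarters,
              x$scheme))
  invisible(x)
}

#' Percentage change between two counts
#'
#' `100 * (after - before) / before`, rounded for reporting (one decimal by
#' default, matching tabular reporting conventions; use `digits = NULL` for
#' the raw value).
#'
#' @param before,after positive counts (before must be > 0).
#' @param digits reporting precision, or `NULL` for unrounded.
#' @return percentage change.
#' @export
percent_change <- function(before, after, digits = 1) {
  if (any(!is.finite(before)) || any(before <= 0)) {
    stop("percent change is undefined for a non-positive baseline")
  }
  pc <- 100 * (after - before) / before
  if (is.null(digits)) pc else round(pc, digits)
}

#' Referrals waiting beyond a threshold
#'
#' Sums the band counts strictly above `threshold_weeks` for one quarter and
#' stratum. The threshold must coincide with a band edge (no interpolation
#' within bands): for the default bands, 12 weeks (the Scottish Government
#' standard) and 52 weeks (one year) are both valid.
#'
#' @param bands a `wait_band_table`.
#' @param threshold_weeks threshold in weeks, on a band edge.
#' @param quarter quarter-end `Date` (or anything `as.Date` parses).
#' @param kind `"ongoing"` (default) or `"completed"`.
#' @return list with `count` (referrals above the threshold), `total`, and
#'   `fraction` (`count / total`, unrounded).
#' @export
exceedance <- function(bands, threshold_weeks, quarter, kind = "ongoing") {
  bdf <- as.data.frame(bands)
  bdf <- bdf[bdf$kind == kind & bdf$quarter_end_date == as.Date(quarter), ,
             drop = FALSE]
  if (!nrow(bdf)) stop("no bands for quarter ", as.Date(quarter))
  if (length(unique(paste(bdf$elective_type, bdf$hb_code, bdf$specialty))) > 1) {
    stop("multiple strata present; subset the band table first")
  }
  edges <- sort(unique(bdf$band_upper[is.finite(bdf$band_upper)]))
  if (!(threshold_weeks %in% edges)) {
    stop("threshold ", threshold_weeks,
         " weeks does not coincide with a band edge (edges: ",
         paste(edges, collapse = ", "), "); no interpolation is performed")
  }
  over <- sum(bdf$count[bdf$band_lower > threshold_weeks])
  total <- sum(bdf$count)
  list(count = over, total = total,
       fraction = if (total > 0) over / total else 0)
}

#' Stratified summary table with threshold flags
#'
#' One row per stratum: the period means of `measure` in `year_before` and
#' `year_after` (same statistic as [quarterly_mean_ci()]), the percentage
#' change between them, and a flag for strata whose change exceeds
#' `change_threshold` (e.g. the ">100% increase in ongoing cases" criterion
#' used to single out the worst-affected boards). Strata with incomplete
#' years are emitted with `NA` markers rather than dropped. If `bands` is
#' supplied, the share of referrals waiting beyond `exceed_weeks` at the end
#' of `year_after` is added with its own flag (default: more than 60% over
#' 12 weeks).
#'
#' @param panel a `waitlist_panel` (multi-stratum).
#' @param by stratum keys to tabulate over, subset of
#'   `c("elective_type", "hb_code", "specialty")`.
#' @param measure measure to summarise.
#' @param year_before,year_after comparison years.
#' @param change_threshold flag threshold for the percentage change (%).
#' @param bands optional `wait_band_table` covering the same strata.
#' @param exceed_weeks,exceed_threshold exceedance threshold (weeks) and
#'   flag level (fraction).
#' @param scheme CI scheme passed to [quarterly_mean_ci()].
#' @return data frame, one row per stratum.
#' @export
stratified_table <- function(panel, by = "hb_code",
                             measure = "pending",
                             year_before, year_after,
                             change_threshold = 100,
                             bands = NULL, exceed_weeks = 12,
                             exceed_threshold = 0.60,
                             scheme = "seasonal") {
  stopifnot(inherits(panel, "waitlist_panel"))
  agg <- aggregate_panel(panel, by = by)
  adf <- as.data.frame(agg)
  keys <- unique(adf[, c("elective_type", "hb_code", "specialty"), drop = FALSE])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- try(panel_subset(agg,
                            elective_type = keys$elective_type[i],
                            hb_code = keys$hb_code[i],
                            specialty = keys$specialty[i]), silent = TRUE)
    mk <- function(y) {
      out <- try(quarterly_mean_ci(sub, measure, y, scheme = scheme),
                 silent = TRUE)
      if (inherits(out, "try-error")) list(mean = NA_real_) else out
    }
    b <- mk(year_before); a <- mk(year_after)
    chg <- if (is.na(b$mean) || is.na(a$mean) || b$mean <= 0) NA_real_ else
      percent_change(b$mean, a$mean)
    data.frame(keys[i, , drop = FALSE],
               mean_before = b$mean, mean_after = a$mean,
               pct_change = chg,
               flag_change = !is.na(chg) & chg > change_threshold,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!is.null(bands)) {
    bdf <- as.data.frame(bands)
    q_end <- quarter_end_date(qcode(year_after, 4))
    frac <- vapply(seq_len(nrow(out)), function(i) {
      sel <- bdf$kind == "ongoing" &
        bdf$quarter_end_date == q_end &
        bdf$elective_type == out$elective_type[i] &
        bdf$hb_code == out$hb_code[i] &
        bdf$specialty == out$specialty[i]
      if (!any(sel)) return(NA_real_)
      sub <- bdf[sel, , drop = FALSE]
      sum(sub$count[sub$band_lower > exceed_weeks]) / sum(sub$count)
    }, 0)
    out$exceed_fraction <- frac
    out$flag_exceed <- !is.na(frac) & frac > exceed_threshold
  }
  out
}
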