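#' Linear capacity ramp for a scenario
#'
#' Quarterly removal path under a gradual, uniform capacity increase
#' accumulating to a fraction `increase` of `baseline` by the end of the
#' horizon: `removals[t] = baseline * (1 + increase * t / horizon)` for
#' `t = 1, ..., horizon`. An increase of 0.20 over a 12-quarter (three-year)
#' horizon therefore corresponds to an annual increase of 20/3 = 6.67
#' percentage points.
#'
#' @param baseline mean quarterly removals in the baseline window (> 0).
#' @param increase total fractional increase reached at the end of the
#'   horizon (must be > -1: capacity cannot go negative).
#' @param horizon number of quarters (>= 1).
#' @return numeric vector of length `horizon`.
#' @export
build_capacity_path <- function(baseline, increase, horizon) {
  if (baseline <= 0) stop("baseline capacity must be positive")
  if (horizon < 1) stop("horizon must be at least one quarter")
  if (increase < -1) stop("capacity increase below -100% would make capacity negative")
  t <- seq_len(horizon)
  baseline * (1 + increase * t / horizon)
}

#' Scenario configuration for waiting-list projections
#'
#' @param capacity_increase total fractional capacity increase accumulated
#'   by the end of the horizon (the policy grid in the recovery analysis is
#'   0 to 0.25 in steps of 0.05).
#' @param horizon projection horizon in quarters (default 12: a three-year
#'   projection, matching the recovery-plan timeline).
#' @param baseline_capacity mean quarterly removals over the baseline
#'   window (by convention the last complete calendar year of data).
#' @param baseline_demand mean quarterly additions over the same window.
#' @param demand_multiplier multiplier on baseline demand over the horizon
#'   (sensitivity grid 0.90, 0.95, 1.00, 1.05, 1.10).
#' @param n_sims Monte Carlo simulation count (default 1000).
#' @param seed integer seed.
#' @param reference_level pre-pandemic pending stock used to judge
#'   clearance (for national data, the end-2019 snapshot; for synthetic
#'   runs, the generator's pre-shock endpoint).
#' @param innovations `"gaussian"` (default, draws from the fitted residual
#'   covariance) or `"bootstrap"` (resampled residuals).
#' @param clearance_on `"median"` (default; matches the headline framing)
#'   or `"upper"` for a conservative check on the 97.5th percentile.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(capacity_increase = 0.20, horizon = 12L,
                            baseline_capacity, baseline_demand,
                            demand_multiplier = 1.0, n_sims = 1000L,
                            seed = 1L, reference_level = NULL,
                            innovations = c("gaussian", "bootstrap"),
                            clearance_on = c("median", "upper")) {
  innovations <- match.arg(innovations)
  clearance_on <- match.arg(clearance_on)
  if (horizon < 1) stop("horizon must be at least one quarter")
  if (n_sims < 1) stop("n_sims must be at least 1")
  if (baseline_capacity <= 0 || baseline_demand <= 0) {
    stop("baseline capacity and demand must be positive")
  }
  out <- list(capacity_increase = capacity_increase,
              horizon = as.integer(horizon),
              baseline_capacity = baseline_capacity,
              baseline_demand = baseline_demand,
              demand_multiplier = demand_multiplier,
              n_sims = as.integer(n_sims), seed = as.integer(seed),
              reference_level = reference_level,
              innovations = innovations, clearance_on = clearance_on)
  class(out) <- "scenario_config"
  out
}

#' Mean quarterly flows over a baseline calendar year
#'
#' @param panel single-stratum `waitlist_panel`.
#' @param year baseline year (all four quarters required).
#' @return list with `capacity` (mean removals), `demand` (mean additions)
#'   and `pending_end` (stock at the year's final quarter).
#' @export
baseline_flows <- function(panel, year) {
  s <- panel_series(panel)
  sel <- which(qcode_year(s$code) == year)
  if (length(sel) != 4) stop("baseline year ", year, " is incomplete")
  list(capacity = mean(s$removals[sel]),
       demand = mean(s$additions[sel]),
       pending_end = s$pending[sel[4]])
}

#' Monte Carlo projection of the waiting list under a capacity scenario
#'
#' Iterates the fitted model forward over the scenario horizon with
#' exogenous additions fixed at `baseline_demand * demand_multiplier` and
#' removals following the linear capacity ramp, adding innovations drawn
#' from the fitted residual covariance (or bootstrap-resampled residuals).
#' The pending stock is floored at zero. Across simulations the 2.5th, 50th
#' and 97.5th percentiles are computed per quarter (the 95% prediction
#' interval is the band between the outer two), together with the peak of
#' the median trajectory and the first quarter, if any, at which the
#' clearance criterion reaches the pre-pandemic reference level.
#'
#' Results are reproducible: the same fit, scenario and seed give
#' bit-identical output. A conservative Monte Carlo error bound for the
#' median trajectory (three times the asymptotic standard error of a sample
#' median) is reported alongside.
#'
#' @param fit a `varx` fit (or [varx_model()] with `init` supplied).
#' @param scenario a [scenario_config()].
#' @param init initial endogenous lags (defaults to the fit's sample tail).
#' @param innovations_array optional pre-drawn `H x n_sims x m` innovation
#'   array, enabling common random numbers across scenarios; overrides the
#'   scenario's innovation setting.
#' @param keep_paths retain the full simulation array in the result.
#' @return a `waitlist_projection`: `$percentiles` (matrix `H x 3`:
#'   `p2.5`, `p50`, `p97.5`), `$peak` (value and quarter on the median),
#'   `$clearance` (flag and first quarter), `$mc_se_median`, the scenario
#'   echo and seed.
#' @export
project_waitlist <- function(fit, scenario, init = NULL,
                             innovations_array = NULL, keep_paths = FALSE) {
  stopifnot(inherits(fit, "varx"), inherits(scenario, "scenario_config"))
  m <- length(fit$endog)
  if (m != 1) {
    stop("scenario projection is defined for a single endogenous series; ",
         "fit the aggregate model or project each type separately")
  }
  H <- scenario$horizon
  removals <- build_capacity_path(scenario$baseline_capacity,
                                  scenario$capacity_increase, H)
  additions <- rep(scenario$baseline_demand * scenario$demand_multiplier, H)
  innov <- innovations_array %||% scenario$innovations
  paths <- simulate.varx(fit, nsim = scenario$n_sims, seed = scenario$seed,
                         additions = additions, removals = removals,
                         init = init, innovations = innov, floor = TRUE)
  pmat <- matrix(paths[, , 1], H, scenario$n_sims)
  qs <- t(apply(pmat, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
                type = 7, names = FALSE))
  colnames(qs) <- c("p2.5", "p50", "p97.5")
  peak_q <- which.max(qs[, "p50"])
  crit <- if (scenario$clearance_on == "median") qs[, "p50"] else qs[, "p97.5"]
  cleared_q <- NA_integer_
  cleared <- FALSE
  if (!is.null(scenario$reference_level)) {
    hit <- which(crit <= scenario$reference_level)
    if (length(hit)) {
      cleared <- TRUE
      cleared_q <- hit[1]
    }
  }
  mc_se <- 3 * 1.2533 * apply(pmat, 1, stats::sd) / sqrt(scenario$n_sims)
  out <- list(
    percentiles = qs,
    peak = list(value = unname(qs[peak_q, "p50"]), quarter = unname(peak_q)),
    clearance = list(cleared = cleared, quarter = cleared_q,
                     reference_level = scenario$reference_level,
                     criterion = scenario$clearance_on),
    mc_se_median = mc_se,
    capacity_path = removals,
    demand_path = additions,
    scenario = scenario,
    seed = scenario$seed
  )
  if (keep_paths) out$paths <- pmat
  class(out) <- "waitlist_projection"
  out
}

#' @export
print.waitlist_projection <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Projection: capacity +%g%% over %d quarters, demand x%.2f, %d sims (seed %d)\n",
              100 * sc$capacity_increase, sc$horizon, sc$demand_multiplier,
              sc$n_sims, x$seed))
  cat(sprintf("  median peak %s in quarter %d of the horizon\n",
              fmt_count(round(x$peak$value)), x$peak$quarter))
  if (!is.null(x$clearance$reference_level)) {
    if (x$clearance$cleared) {
      cat(sprintf("  clears to the reference level (%s) in quarter %d [%s criterion]\n",
                  fmt_count(round(x$clearance$reference_level)),
                  x$clearance$quarter, x$clearance$criterion))
    } else {
      cat(sprintf("  does not reach the reference level (%s) within the horizon\n",
                  fmt_count(round(x$clearance$reference_level))))
    }
  }
  invisible(x)
}

#' @export
plot.waitlist_projection <- function(x, ...) {
  H <- nrow(x$percentiles)
  graphics::matplot(seq_len(H), x$percentiles, type = "l",
                    lty = c(2, 1, 2), col = c("grey40", "black", "grey40"),
                    xlab = "quarters ahead", ylab = "pending referrals",
                    main = sprintf("Capacity +%g%%: median and 95%% prediction interval",
                                   100 * x$scenario$capacity_increase), ...)
  if (!is.null(x$clearance$reference_level)) {
    graphics::abline(h = x$clearance$reference_level, col = "red3", lty = 3)
  }
  invisible(x)
}

#' Smallest capacity increase on a grid that clears the backlog
#'
#' Projects every grid value with common random numbers (one innovation
#' array drawn from the scenario seed and shared across scenarios, so
#' scenario differences are not confounded with simulation noise) and
#' returns the smallest increase whose trajectory reaches the pre-pandemic
#' reference level within the horizon, together with the full scenario
#' table (peak value and quarter, clearance quarter per grid point). If no
#' grid value clears, the result records that rather than raising an error.
#'
#' @param fit a `varx` fit.
#' @param grid sorted capacity-increase fractions (default 0 to 0.25 by
#'   0.05).
#' @param scenario baseline [scenario_config()]; its `capacity_increase` is
#'   overridden by each grid value.
#' @param reference_level pre-pandemic pending level defining clearance
#'   (overrides the scenario's).
#' @param init initial lags passed to [project_waitlist()].
#' @return a `capacity_search`: `$min_increase` (smallest clearing fraction
#'   or `NA` if none on the grid), `$table`, `$projections`.
#' @export
find_min_capacity_increase <- function(fit, grid = seq(0, 0.25, by = 0.05),
                                       scenario, reference_level = NULL,
                                       init = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (!length(grid)) stop("capacity grid is empty")
  if (is.unsorted(grid)) stop("capacity grid must be sorted increasing")
  reference_level <- reference_level %||% scenario$reference_level
  if (is.null(reference_level) || reference_level <= 0) {
    stop("a positive pre-pandemic reference level is required")
  }
  H <- scenario$horizon
  # common random numbers: one innovation draw shared by all grid points
  eps <- with_seed(scenario$seed, {
    sig <- fit$sigma
    if (all(sig == 0)) {
      array(0, c(H, scenario$n_sims, 1))
    } else if (scenario$innovations == "bootstrap") {
      idx <- sample.int(nrow(fit$residuals), H * scenario$n_sims, replace = TRUE)
      array(fit$residuals[idx, 1], c(H, scenario$n_sims, 1))
    } else {
      array(stats::rnorm(H * scenario$n_sims, 0, sqrt(drop(sig))),
            c(H, scenario$n_sims, 1))
    }
  })
  projections <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    sc <- scenario
    sc$capacity_increase <- grid[i]
    sc$reference_level <- reference_level
    pr <- project_waitlist(fit, sc, init = init, innovations_array = eps)
    projections[[i]] <- pr
    rows[[i]] <- data.frame(
      capacity_increase = grid[i],
      peak_value = pr$peak$value,
      peak_quarter = pr$peak$quarter,
      cleared = pr$clearance$cleared,
      clearance_quarter = pr$clearance$quarter
    )
  }
  tab <- do.call(rbind, rows)
  cleared <- which(tab$cleared)
  out <- list(
    min_increase = if (length(cleared)) grid[cleared[1]] else NA_real_,
    table = tab,
    projections = projections,
    reference_level = reference_level
  )
  class(out) <- "capacity_search"
  out
}

#' @export
print.capacity_search <- function(x, ...) {
  cat("Minimum capacity increase to clear the pandemic backlog (reference ",
      fmt_count(round(x$reference_level)), "):\n", sep = "")
  print(x$table, row.names = FALSE, digits = 6)
  if (is.na(x$min_increase)) {
    cat("\nNo grid value clears the backlog within the horizon.\n")
  } else {
    cat(sprintf("\nSmallest clearing increase on the grid: %g%%\n",
                100 * x$min_increase))
  }
  invisible(x)
}

#' Pre-pandemic linear counterfactual
#'
#' Ordinary least-squares straight line of the pending stock on the quarter
#' index over a pre-pandemic window, extrapolated forward: the trajectory
#' the waiting list would have followed had the pre-pandemic trend simply
#' continued.
#'
#' @param panel single-stratum `waitlist_panel`.
#' @param window_start,window_end quarter-end `Date`s bounding the fit
#'   window (inclusive); defaults to 2013 Q1 through 2019 Q4.
#' @param projection_end quarter-end `Date` up to which the line is
#'   extrapolated.
#' @return a `linear_counterfactual` list: `slope` (referrals per quarter),
#'   `intercept`, fitted window values and the extrapolated trajectory with
#'   quarter labels.
#' @export
linear_counterfactual <- function(panel,
                                  window_start = as.Date("2013-03-31"),
                                  window_end = as.Date("2019-12-31"),
                                  projection_end) {
  s <- panel_series(panel)
  c0 <- date_qcode(window_start)
  c1 <- date_qcode(window_end)
  sel <- which(s$code >= c0 & s$code <= c1)
  if (length(sel) < 3) {
    stop("counterfactual window has ", length(sel),
         " quarters; at least 3 are required")
  }
  idx <- s$code[sel] - s$code[sel][1] + 1
  fit <- stats::lm(s$pending[sel] ~ idx)
  co <- stats::coef(fit)
  end_code <- date_qcode(projection_end)
  all_codes <- s$code[sel][1]:end_code
  all_idx <- all_codes - s$code[sel][1] + 1
  traj <- co[1] + co[2] * all_idx
  out <- list(
    slope = unname(co[2]),
    intercept = unname(co[1]),
    annualised_slope = unname(co[2]) * 4,
    window = quarter_label(s$code[sel]),
    trajectory = data.frame(
      quarter_end_date = quarter_end_date(all_codes),
      quarter = quarter_label(all_codes),
      counterfactual = unname(traj)
    )
  )
  class(out) <- "linear_counterfactual"
  out
}

#' @export
print.linear_counterfactual <- function(x, ...) {
  cat(sprintf("Pre-pandemic linear counterfactual: slope %.1f referrals/quarter (%.0f/year)\n",
              x$slope, x$annualised_slope))
  cat("Window: ", x$window[1], " to ", x$window[length(x$window)],
      "; extrapolated to ",
      x$trajectory$quarter[nrow(x$trajectory)], "\n", sep = "")
  invisible(x)
}
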