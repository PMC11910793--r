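#' Configuration for the synthetic waiting-list generator
#'
#' Describes a quarterly stock-flow regime with the features national
#' elective-care data exhibit: an approximately linear pre-shock trend in the
#' pending stock (driven by persistent net inflow), additive quarter-of-year
#' seasonality in the flows, and a sudden collapse in throughput with slow
#' partial recovery.
#'
#' The defaults emulate Scotland's national series over 2013--2023 at the
#' aggregate scale: 44 quarters starting 2013 Q1, initial stock 254,612,
#' baseline inflow 436,400 and outflow 432,650 per quarter (net inflow 3,750
#' a quarter, i.e. roughly 15,000 referrals a year), a capacity collapse of
#' depth 0.67 in quarter 30 (2020 Q2) recovering at 0.055 of the lost depth
#' per quarter (leaving throughput roughly 15% below baseline after four
#' years), and flow noise of a percent or two of the baselines.
#'
#' @param n_quarters number of quarters to generate.
#' @param start_year,start_quarter calendar position of the first quarter.
#' @param baseline_additions,baseline_removals mean inflow/outflow per
#'   quarter (referrals).
#' @param inflow_trend additive change in mean inflow per quarter
#'   (referrals/quarter); outflow keeps its baseline.
#' @param seasonal_additions,seasonal_removals length-4 additive
#'   quarter-of-year offsets (referrals); each must sum to zero.
#' @param shock_quarter 1-based index of the capacity collapse, or `NA` for
#'   no shock.
#' @param shock_depth fractional outflow reduction at the shock, in `[0, 1]`.
#' @param recovery_rate fraction of the shock depth recovered per subsequent
#'   quarter, in `[0, 1]`.
#' @param additions_shock_multiplier optional transient multiplier applied to
#'   inflow in the shock quarter only (default 1: the disruption is to
#'   throughput, not demand).
#' @param noise_sd_additions,noise_sd_removals innovation standard deviations
#'   of the flows (referrals).
#' @param initial_pending starting stock (referrals, non-negative).
#' @param strata list of stratum descriptors, each a list with
#'   `elective_type`, `hb_code`, `specialty`, `weight` (positive relative
#'   weight). Baselines, seasonal offsets, noise sds and the initial stock
#'   are scaled by the normalised weights.
#' @param seed integer seed; fixing it fixes every generated number.
#' @return a `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_quarters = 44L,
                             start_year = 2013L,
                             start_quarter = 1L,
                             baseline_additions = 436400,
                             baseline_removals = 432650,
                             inflow_trend = 0,
                             seasonal_additions = c(15000, 5000, -8000, -12000),
                             seasonal_removals = c(12000, 8000, -9000, -11000),
                             shock_quarter = 30L,
                             shock_depth = 0.67,
                             recovery_rate = 0.055,
                             additions_shock_multiplier = 1,
                             noise_sd_additions = 6000,
                             noise_sd_removals = 5000,
                             initial_pending = 254612,
                             strata = list(list(elective_type = "all",
                                                hb_code = "Scotland",
                                                specialty = "all",
                                                weight = 1)),
                             seed = 1L) {
  cfg <- list(
    n_quarters = as.integer(n_quarters),
    start_year = as.integer(start_year),
    start_quarter = as.integer(start_quarter),
    baseline_additions = baseline_additions,
    baseline_removals = baseline_removals,
    inflow_trend = inflow_trend,
    seasonal_additions = seasonal_additions,
    seasonal_removals = seasonal_removals,
    shock_quarter = if (is.na(shock_quarter)) NA_integer_ else as.integer(shock_quarter),
    shock_depth = shock_depth,
    recovery_rate = recovery_rate,
    additions_shock_multiplier = additions_shock_multiplier,
    noise_sd_additions = noise_sd_additions,
    noise_sd_removals = noise_sd_removals,
    initial_pending = initial_pending,
    strata = strata,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_quarters >= 1, cfg$start_quarter %in% 1:4)
  if (cfg$initial_pending < 0) stop("initial_pending must be non-negative")
  tol <- 1e-9 * max(1, cfg$baseline_additions, cfg$baseline_removals)
  for (nm in c("seasonal_additions", "seasonal_removals")) {
    s <- cfg[[nm]]
    if (length(s) != 4) stop(nm, " must have four quarter-of-year offsets")
    if (abs(sum(s)) > tol) stop(nm, " must sum to zero (got ", sum(s), ")")
  }
  if (cfg$shock_depth < 0 || cfg$shock_depth > 1) {
    stop("shock_depth must lie in [0, 1]")
  }
  if (cfg$recovery_rate < 0 || cfg$recovery_rate > 1) {
    stop("recovery_rate must lie in [0, 1]")
  }
  if (cfg$noise_sd_additions < 0 || cfg$noise_sd_removals < 0) {
    stop("noise standard deviations must be non-negative")
  }
  w <- vapply(cfg$strata, function(s) as.numeric(s$weight %||% NA_real_), 0)
  if (anyNA(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop("stratum weights must be positive and finite")
  }
  invisible(cfg)
}

#' Generate a synthetic waiting-list panel
#'
#' Draws quarterly inflow and outflow per stratum around the configured
#' baselines (trend + additive quarter-of-year seasonality + Gaussian
#' noise), applies the capacity-shock regime to outflow, floors negative
#' draws at zero, rounds half-to-even, and accumulates the pending stock by
#' the accounting identity `pending[t] = pending[t-1] + additions[t] -
#' removals[t]` on the rounded flows, so stock-flow conservation holds
#' exactly on the returned panel. Removals that would drive the stock
#' negative are truncated to the available stock; all flooring and
#' truncation shortfalls are recorded in the `"shortfall_log"` attribute,
#' never redistributed.
#'
#' From the shock quarter onwards the outflow baseline is multiplied by
#' `1 - shock_depth * max(0, 1 - recovery_rate * quarters_since_shock)`,
#' where `quarters_since_shock` is 0 in the shock quarter itself; seasonality
#' and noise are added after the multiplier.
#'
#' @param config a [synthetic_config()].
#' @return a `waitlist_panel` with exact conservation; the generating
#'   configuration is stored in the `"config"` attribute.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  w <- vapply(config$strata, function(s) as.numeric(s$weight), 0)
  w <- w / sum(w)
  n <- config$n_quarters
  codes <- qcode_seq(config$start_year, config$start_quarter, n)
  qoy <- qcode_quarter(codes)
  t_idx <- seq_len(n)

  shock_factor <- rep(1, n)
  if (!is.na(config$shock_quarter)) {
    since <- t_idx - config$shock_quarter
    hit <- since >= 0
    shock_factor[hit] <- 1 - config$shock_depth *
      pmax(0, 1 - config$recovery_rate * since[hit])
  }
  add_mult <- rep(1, n)
  if (!is.na(config$shock_quarter)) {
    add_mult[t_idx == config$shock_quarter] <- config$additions_shock_multiplier
  }

  rows <- vector("list", length(config$strata))
  shortfalls <- list()
  with_seed(config$seed, {
    for (i in seq_along(config$strata)) {
      st <- config$strata[[i]]
      mu_add <- (config$baseline_additions + config$inflow_trend * (t_idx - 1) +
                   config$seasonal_additions[qoy]) * w[i] * add_mult
      mu_rem <- (config$baseline_removals * shock_factor +
                   config$seasonal_removals[qoy]) * w[i]
      add <- mu_add + stats::rnorm(n, 0, config$noise_sd_additions * w[i])
      rem <- mu_rem + stats::rnorm(n, 0, config$noise_sd_removals * w[i])
      floor_short <- sum(pmin(add, 0)) + sum(pmin(rem, 0))
      add <- round(pmax(add, 0))
      rem <- round(pmax(rem, 0))
      p0 <- round(config$initial_pending * w[i])
      pending <- numeric(n)
      trunc_short <- 0
      prev <- p0
      for (t in t_idx) {
        avail <- prev + add[t]
        if (rem[t] > avail) {
          trunc_short <- trunc_short + (rem[t] - avail)
          rem[t] <- avail
        }
        pending[t] <- prev + add[t] - rem[t]
        prev <- pending[t]
      }
      shortfalls[[i]] <- data.frame(
        stratum = paste(st$elective_type, st$hb_code, st$specialty, sep = "|"),
        floored = -floor_short, truncated = trunc_short
      )
      rows[[i]] <- data.frame(
        quarter_end_date = quarter_end_date(codes),
        elective_type = st$elective_type,
        hb_code = st$hb_code,
        specialty = st$specialty,
        additions = add,
        removals = rem,
        pending = pending,
        stringsAsFactors = FALSE
      )
    }
  })
  panel <- waitlist_panel(do.call(rbind, rows), conserve = TRUE)
  attr(panel, "config") <- config
  attr(panel, "shortfall_log") <- do.call(rbind, shortfalls)
  panel
}

#' Simulate a panel from a known vector-autoregressive process
#'
#' Companion to [generate_panel()] for simulation studies with known
#' coefficients: exogenous inflow and outflow are drawn around fixed
#' baselines with additive quarter-of-year seasonality and Gaussian noise,
#' and the pending stock then follows the model recursion of `model` (its
#' autoregressive lags, exogenous coefficients and intercept) plus a process
#' innovation with the model's residual standard deviation. Unlike
#' [generate_panel()], the stock is *not* tied to the flows by the
#' accounting identity, so estimation on such panels faces genuine
#' regression error; the reconciliation residual is stored, as for observed
#' data.
#'
#' @param model a coefficient specification from [varx_model()]
#'   (single endogenous series).
#' @param n_quarters length of the simulated panel.
#' @param baseline_additions,baseline_removals exogenous flow baselines.
#' @param seasonal_additions,seasonal_removals length-4 zero-sum offsets.
#' @param flow_sd standard deviation of the exogenous flow noise.
#' @param initial_pending pre-sample stock level used for all initial lags.
#' @param start_year,start_quarter calendar position of the first quarter.
#' @param seed integer seed.
#' @return a `waitlist_panel` (one stratum, `all|Scotland|all`).
#' @export
simulate_panel <- function(model, n_quarters,
                           baseline_additions = 5000,
                           baseline_removals = 5000,
                           seasonal_additions = c(600, 200, -300, -500),
                           seasonal_removals = c(500, 300, -350, -450),
                           flow_sd = 200,
                           initial_pending = 10000,
                           start_year = 2013L, start_quarter = 1L,
                           seed = 1L) {
  stopifnot(inherits(model, "varx"), length(model$endog) == 1)
  n <- as.integer(n_quarters)
  codes <- qcode_seq(start_year, start_quarter, n)
  qoy <- qcode_quarter(codes)
  maxlag <- max(model$lags)
  sd_innov <- sqrt(drop(model$sigma))
  with_seed(seed, {
    add <- pmax(baseline_additions + seasonal_additions[qoy] +
                  stats::rnorm(n, 0, flow_sd), 0)
    rem <- pmax(baseline_removals + seasonal_removals[qoy] +
                  stats::rnorm(n, 0, flow_sd), 0)
    eps <- stats::rnorm(n, 0, sd_innov)
    pending <- numeric(n + maxlag)
    pending[seq_len(maxlag)] <- initial_pending
    phi <- vapply(model$phi, function(m) drop(m), 0)
    beta <- drop(model$beta)  # order: additions, removals
    for (t in seq_len(n)) {
      i <- t + maxlag
      ar <- sum(phi * pending[i - model$lags])
      pending[i] <- max(0, drop(model$intercept) + ar +
                          beta[1] * add[t] + beta[2] * rem[t] + eps[t])
    }
  })
  df <- data.frame(
    quarter_end_date = quarter_end_date(codes),
    elective_type = "all", hb_code = "Scotland", specialty = "all",
    additions = round(add), removals = round(rem),
    pending = round(pending[maxlag + seq_len(n)]),
    stringsAsFactors = FALSE
  )
  panel <- waitlist_panel(df)
  attr(panel, "model") <- model
  panel
}

#' Generate wait-duration band tables for a panel
#'
#' Tracks referral cohorts by entry quarter with exact bookkeeping: a
#' quarter is 13 weeks, so a cohort that entered in quarter `t` has waited
#' between `13k` and `13(k+1)` weeks at the end of quarter `t + k` and its
#' band follows deterministically from its age. Each quarter the panel's
#' additions enter as a new cohort, and the panel's removals are allocated
#' across cohorts proportionally to the aging profile's per-band resolution
#' share times the cohort size (largest-remainder integer apportionment,
#' capped at cohort size with spill-over to the remaining stock). Ongoing
#' band counts therefore sum exactly to the panel's pending stock in every
#' quarter, and completed band counts to its removals.
#'
#' The default bands are 0--12 weeks, 13--52 weeks and over 52 weeks,
#' matching the Scottish Government 12-week standard and the one-year
#' threshold.
#'
#' @param panel a single-stratum `waitlist_panel` (subset or aggregate
#'   first); initial stock is treated as a cohort that entered just before
#'   the first quarter.
#' @param aging_profile square matrix (bands x bands) of band-transition
#'   fractions: rows non-negative, each row summing to at most 1; the
#'   remainder `1 - rowSums` is the band's resolution share, which sets the
#'   relative propensity of its referrals to be removed. Band movement
#'   itself is governed by cohort age (see above), so the off-diagonal
#'   entries only need to respect band order. A plain numeric vector of
#'   per-band resolution shares is also accepted.
#' @param seed integer seed (used to break apportionment ties).
#' @param band_lower lower band edges in weeks, first 0, strictly
#'   increasing; bands are contiguous and the last is open-ended.
#' @return a `wait_band_table` data frame with columns `quarter_end_date`,
#'   stratum keys, `kind` (`"ongoing"` or `"completed"`), `band_lower`,
#'   `band_upper` (Inf for the open band) and `count`.
#' @export
generate_wait_bands <- function(panel, aging_profile, seed = 1L,
                                band_lower = c(0, 13, 53)) {
  stopifnot(inherits(panel, "waitlist_panel"))
  s <- panel_series(panel)
  nb <- length(band_lower)
  if (nb < 2 || band_lower[1] != 0 || any(diff(band_lower) <= 0)) {
    stop("band_lower must start at 0 and be strictly increasing")
  }
  if (is.matrix(aging_profile)) {
    if (nrow(aging_profile) != nb || ncol(aging_profile) != nb) {
      stop("aging_profile must be ", nb, " x ", nb, " to match the bands")
    }
    if (any(aging_profile < 0)) stop("aging_profile entries must be non-negative")
    rs <- rowSums(aging_profile)
    if (any(rs > 1 + 1e-9)) stop("aging_profile rows must sum to at most 1")
    resolve_share <- pmax(0, 1 - rs)
  } else {
    if (length(aging_profile) != nb || any(aging_profile < 0) ||
        any(aging_profile > 1)) {
      stop("per-band resolution shares must be in [0, 1], one per band")
    }
    resolve_share <- as.numeric(aging_profile)
  }

  n <- length(s$code)
  # cohort j = entered in quarter j; cohort 0 = initial stock
  cohort <- c(s$pending[1] - s$additions[1] + s$removals[1], rep(0, n))
  if (cohort[1] < 0) {
    # first-quarter removals exceeded initial stock + additions cannot occur
    # on a valid panel; guard anyway
    cohort[1] <- 0
  }
  names(cohort) <- 0:n
  band_of_age <- function(age) findInterval(13 * age + 1, band_lower)

  ongoing <- matrix(0L, n, nb)
  completed <- matrix(0L, n, nb)
  with_seed(seed, {
    for (t in seq_len(n)) {
      cohort[t + 1] <- s$additions[t]
      ages <- t - (0:n)           # cohort 0 has age t (entered pre-study)
      live <- which(cohort > 0 & ages >= 0)
      bands <- band_of_age(pmin(ages[live], (max(band_lower) %/% 13) + 1))
      R <- s$removals[t]
      if (R > 0) {
        if (sum(cohort[live]) < R) {
          stop("cannot reconcile removals with the waiting stock in ",
               quarter_label(s$code[t]), ": removals ", R,
               " exceed the ", sum(cohort[live]), " referrals on the list")
        }
        wts <- resolve_share[bands] * cohort[live]
        if (sum(wts) == 0) {
          stop("cannot reconcile removals with the aging profile in ",
               quarter_label(s$code[t]),
               ": removals are ", R, " but every band's resolution share is 0")
        }
        # random tie-break: jitter weights infinitesimally
        wts <- wts * (1 + stats::runif(length(wts)) * 1e-12)
        res <- integer_allocate(R, wts, cap = cohort[live])
        cohort[live] <- cohort[live] - res
        completed[t, ] <- completed[t, ] +
          as.integer(tapply(res, factor(bands, levels = seq_len(nb)), sum,
                            default = 0L))
      }
      live2 <- which(cohort > 0)
      if (length(live2)) {
        b2 <- band_of_age(pmin(t - (0:n)[live2], (max(band_lower) %/% 13) + 1))
        ongoing[t, ] <- as.integer(tapply(cohort[live2],
                                          factor(b2, levels = seq_len(nb)),
                                          sum, default = 0L))
      }
    }
  })

  st <- as.data.frame(panel)[1, c("elective_type", "hb_code", "specialty")]
  upper <- c(band_lower[-1] - 1, Inf)
  mk <- function(mat, kind) {
    data.frame(
      quarter_end_date = rep(quarter_end_date(s$code), each = nb),
      elective_type = st$elective_type, hb_code = st$hb_code,
      specialty = st$specialty, kind = kind,
      band_lower = rep(band_lower, n),
      band_upper = rep(upper, n),
      count = as.vector(t(mat)),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(mk(ongoing, "ongoing"), mk(completed, "completed"))
  class(out) <- c("wait_band_table", "data.frame")
  # by construction the partitions are exact; validate anyway
  out <- validate_band_table(out, panel, tolerance = 0)
  out
}
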