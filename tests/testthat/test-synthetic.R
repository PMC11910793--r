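test_that("balanced flows keep the stock constant and net inflow accumulates linearly", {
  balanced <- synthetic_config(
    n_quarters = 12, baseline_additions = 1000, baseline_removals = 1000,
    inflow_trend = 0, seasonal_additions = rep(0, 4), seasonal_removals = rep(0, 4),
    shock_quarter = NA, noise_sd_additions = 0, noise_sd_removals = 0,
    initial_pending = 5000, seed = 1
  )
  expect_equal(pending_of(generate_panel(balanced)), rep(5000, 12))

  surplus <- synthetic_config(
    n_quarters = 8, baseline_additions = 1000, baseline_removals = 900,
    inflow_trend = 0, seasonal_additions = rep(0, 4), seasonal_removals = rep(0, 4),
    shock_quarter = NA, noise_sd_additions = 0, noise_sd_removals = 0,
    initial_pending = 0, seed = 1
  )
  p <- pending_of(generate_panel(surplus))
  expect_equal(p[8], 800)
  expect_equal(p, 100 * (1:8))
})

test_that("zero-noise generation matches an independent reference recursion exactly", {
  cfg <- synthetic_config(
    n_quarters = 16, baseline_additions = 2000, baseline_removals = 1900,
    inflow_trend = 10,
    seasonal_additions = c(100, 50, -50, -100),
    seasonal_removals = c(80, 20, -40, -60),
    shock_quarter = 9, shock_depth = 0.5, recovery_rate = 0.1,
    noise_sd_additions = 0, noise_sd_removals = 0,
    initial_pending = 10000, seed = 1
  )
  panel <- generate_panel(cfg)
  s <- waitlistr:::panel_series(panel)
  # reference recursion, written independently of the generator
  pend <- 10000
  for (t in 1:16) {
    q <- (t - 1) %% 4 + 1
    add <- 2000 + 10 * (t - 1) + c(100, 50, -50, -100)[q]
    fac <- if (t >= 9) 1 - 0.5 * max(0, 1 - 0.1 * (t - 9)) else 1
    rem <- 1900 * fac + c(80, 20, -40, -60)[q]
    expect_equal(s$additions[t], round(add))
    expect_equal(s$removals[t], round(rem))
    pend <- pend + round(add) - round(rem)
    expect_equal(s$pending[t], pend)
  }
})

test_that("stock-flow conservation holds exactly on every stratum and seeds are reproducible", {
  strata <- list(
    list(elective_type = "inpatient", hb_code = "S08000015", specialty = "all", weight = 0.2),
    list(elective_type = "outpatient", hb_code = "S08000015", specialty = "all", weight = 0.5),
    list(elective_type = "outpatient", hb_code = "S08000016", specialty = "all", weight = 0.3)
  )
  for (sd in 1:5) {
    cfg <- synthetic_config(n_quarters = 24, strata = strata, seed = sd)
    panel <- generate_panel(cfg)
    res <- panel_conservation(panel)$residual
    expect_true(all(res[!is.na(res)] == 0))
    expect_true(all(panel$additions >= 0 & panel$removals >= 0 & panel$pending >= 0))
    expect_true(all(panel[c("additions", "removals", "pending")] ==
                      round(panel[c("additions", "removals", "pending")])))
  }
  cfg <- synthetic_config(seed = 99)
  expect_identical(as.data.frame(generate_panel(cfg)),
                   as.data.frame(generate_panel(cfg)))
  expect_false(identical(
    as.data.frame(generate_panel(synthetic_config(seed = 1)))$additions,
    as.data.frame(generate_panel(synthetic_config(seed = 2)))$additions
  ))
})

test_that("study-emulating panel grows at the configured net inflow (cumulative-sum oracle)", {
  # the stock is exactly the cumulative sum of drawn net inflows, and the
  # mean pre-shock growth is the configured net inflow up to sampling noise
  growths <- vapply(1:100, function(sd) {
    panel <- generate_panel(synthetic_config(seed = sd))
    s <- waitlistr:::panel_series(panel)
    cfg <- attr(panel, "config")
    expect_equal(s$pending,
                 cfg$initial_pending + cumsum(s$additions - s$removals))
    (s$pending[28] - cfg$initial_pending) / 28
  }, 0)
  net_inflow <- 436400 - 432650
  flow_sd <- sqrt(6000^2 + 5000^2)
  se <- flow_sd / sqrt(28) / sqrt(100)
  expect_lt(abs(mean(growths) - net_inflow), 2 * se + 1)  # +1 for rounding
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(initial_pending = -1), "non-negative")
  expect_error(synthetic_config(shock_depth = 1.2), "0, 1")
  expect_error(synthetic_config(recovery_rate = -0.1), "0, 1")
  expect_error(synthetic_config(seasonal_additions = c(1, 2, 3, 4)), "sum to zero")
  expect_error(synthetic_config(strata = list(list(elective_type = "all",
                                                   hb_code = "x", specialty = "all",
                                                   weight = 0))),
               "positive")
  expect_error(synthetic_config(strata = list(list(elective_type = "all",
                                                   hb_code = "x", specialty = "all",
                                                   weight = Inf))),
               "finite")
})

test_that("full within-quarter resolution leaves nothing waiting over 12 weeks", {
  # removals always clear the entire list, so the ongoing table is empty
  additions <- rep(100, 10)
  removals <- c(150, rep(100, 9))          # clears initial stock too
  panel <- toy_panel(additions, removals, pending0 = 50)
  bands <- generate_wait_bands(panel, aging_profile = matrix(0, 3, 3), seed = 1)
  ongoing <- bands[bands$kind == "ongoing", ]
  expect_true(all(ongoing$count[ongoing$band_lower > 12] == 0))
  completed <- bands[bands$kind == "completed", ]
  sums <- tapply(completed$count, completed$quarter_end_date, sum)
  expect_equal(as.numeric(sums), removals)
})

test_that("zero resolution accumulates all stock into the top band (cohort oracle)", {
  n <- 10
  additions <- seq(10, 100, by = 10)
  panel <- toy_panel(additions, removals = rep(0, n), pending0 = 0)
  profile <- matrix(0, 3, 3)
  profile[1, 2] <- 1; profile[2, 3] <- 1; profile[3, 3] <- 1  # rows sum to 1
  bands <- generate_wait_bands(panel, aging_profile = profile, seed = 1)
  ongoing <- bands[bands$kind == "ongoing", ]
  final <- ongoing[ongoing$quarter_end_date == max(ongoing$quarter_end_date), ]
  expect_equal(final$count[final$band_lower == 53], sum(additions[1:(n - 4)]))
  # explicit cohort bookkeeping oracle for the whole table: cohort of age k
  # has waited 13k..13(k+1) weeks at quarter end
  for (t in 1:n) {
    ages <- t - seq_len(t)
    oracle <- c(sum(additions[seq_len(t)][ages == 0]),
                sum(additions[seq_len(t)][ages >= 1 & ages <= 3]),
                sum(additions[seq_len(t)][ages >= 4]))
    got <- ongoing[ongoing$quarter_end_date ==
                     sort(unique(ongoing$quarter_end_date))[t], ]
    expect_equal(got$count[order(got$band_lower)], oracle)
  }
})

test_that("band tables always partition the stock and throughput", {
  panel <- generate_panel(synthetic_config(n_quarters = 20, seed = 7))
  bands <- generate_wait_bands(panel, aging_profile = c(0.8, 0.5, 0.3), seed = 2)
  s <- waitlistr:::panel_series(panel)
  ongoing <- bands[bands$kind == "ongoing", ]
  completed <- bands[bands$kind == "completed", ]
  expect_equal(as.numeric(tapply(ongoing$count, ongoing$quarter_end_date, sum)),
               s$pending)
  expect_equal(as.numeric(tapply(completed$count, completed$quarter_end_date, sum)),
               s$removals)
  expect_true(all(bands$count >= 0))
  # a profile with no resolution anywhere cannot reconcile positive removals
  expect_error(
    generate_wait_bands(panel, aging_profile = c(0, 0, 0), seed = 1),
    "cannot reconcile removals.*2013 Q1"
  )
})

test_that("known-coefficient panel simulator is seeded and stores reconciliation residuals", {
  truth <- study_truth()
  a <- simulate_panel(truth, 20, seed = 5)
  b <- simulate_panel(truth, 20, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  res <- panel_conservation(a)$residual
  expect_true(any(res[!is.na(res)] != 0))  # process noise breaks the identity
})
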