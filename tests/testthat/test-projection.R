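test_that("capacity ramp is linear, uniform and correctly annualised", {
  path <- build_capacity_path(100, 0.20, 12)
  expect_equal(length(path), 12)
  expect_equal(path[12], 120)
  expect_equal(unique(round(diff(path), 10)), 100 * 0.20 / 12)
  expect_equal(build_capacity_path(100, 0, 12), rep(100, 12))
  # 20% over three years is 6.67% per year
  expect_equal(round(100 * 0.20 / 3, 2), 6.67)
  expect_error(build_capacity_path(100, -1.5, 12), "-100%")
  expect_error(build_capacity_path(0, 0.1, 12), "positive")
  expect_error(build_capacity_path(100, 0.1, 0), "horizon")
})

test_that("degenerate (zero-covariance) projections equal a hand-rolled recursion", {
  model <- varx_model(lags = c(1, 4), phi = c(0.6, 0.25), beta = c(0.9, -0.85),
                      intercept = 300, sigma = 0)
  init <- matrix(c(900, 950, 1000, 1050), ncol = 1)
  sc <- scenario_config(0.15, 12, baseline_capacity = 120,
                        baseline_demand = 130, n_sims = 25, seed = 3,
                        reference_level = 500)
  pr <- project_waitlist(model, sc, init = init)
  # independent recursion, coded directly from the scenario definition
  rem <- 120 * (1 + 0.15 * (1:12) / 12)
  addv <- rep(130, 12)
  hist <- c(900, 950, 1000, 1050)
  oracle <- numeric(12)
  for (t in 1:12) {
    y <- 300 + 0.6 * hist[length(hist)] + 0.25 * hist[length(hist) - 3] +
      0.9 * addv[t] - 0.85 * rem[t]
    y <- max(y, 0)
    hist <- c(hist, y)
    oracle[t] <- y
  }
  expect_equal(unname(pr$percentiles[, "p50"]), oracle)
  expect_equal(unname(pr$percentiles[, "p2.5"]), oracle)   # all sims identical
  expect_equal(unname(pr$percentiles[, "p97.5"]), oracle)
  expect_equal(pr$peak$value, max(oracle))
  expect_equal(pr$peak$quarter, which.max(oracle))
})

test_that("the accounting-identity model matches its closed form", {
  sc <- scenario_config(0, 12, baseline_capacity = 100, baseline_demand = 110,
                        n_sims = 200, seed = 2, reference_level = 1)
  pr <- project_waitlist(identity_model(), sc, init = matrix(1000))
  # net inflow 10/quarter for 12 quarters from 1000
  expect_equal(unname(pr$percentiles[, "p50"]), 1000 + 10 * (1:12))
  expect_equal(unname(pr$percentiles[12, "p50"]), 1120)
})

test_that("projections are bit-reproducible under a fixed seed", {
  pan <- simulate_panel(study_truth(), 44, seed = 5)
  f <- varx(pan, lags = c(1, 4))
  bl <- baseline_flows(pan, 2023)
  sc <- scenario_config(0.1, 12, bl$capacity, bl$demand, n_sims = 300,
                        seed = 11, reference_level = bl$pending_end)
  a <- project_waitlist(f, sc)
  b <- project_waitlist(f, sc)
  expect_identical(a$percentiles, b$percentiles)
  expect_identical(a$peak, b$peak)
  expect_identical(a$clearance, b$clearance)
  sc2 <- sc; sc2$seed <- 12L
  expect_false(identical(project_waitlist(f, sc2)$percentiles, a$percentiles))
})

test_that("percentile ordering holds and capacity is monotone under common random numbers", {
  pan <- simulate_panel(study_truth(), 44, seed = 8)
  f <- varx(pan, lags = c(1, 4))
  bl <- baseline_flows(pan, 2023)
  sc <- scenario_config(0, 12, bl$capacity, bl$demand, n_sims = 400,
                        seed = 21, reference_level = bl$pending_end * 0.9)
  search <- find_min_capacity_increase(f, grid = seq(0, 0.25, 0.05),
                                       scenario = sc)
  meds <- sapply(search$projections, function(p) p$percentiles[, "p50"])
  for (p in search$projections) {
    q <- p$percentiles
    expect_true(all(q[, "p2.5"] <= q[, "p50"] & q[, "p50"] <= q[, "p97.5"]))
    expect_equal(p$peak$value, max(q[, "p50"]))
  }
  # per-quarter medians and the median peak never increase with capacity
  expect_true(all(apply(meds, 1, function(r) all(diff(r) <= 1e-9))))
  expect_true(all(diff(search$table$peak_value) <= 1e-9))
})

test_that("a wider innovation covariance never narrows the prediction interval", {
  narrow <- varx_model(lags = 1, phi = 0.8, beta = c(0.9, -0.9),
                       intercept = 100, sigma = 50^2)
  wide <- varx_model(lags = 1, phi = 0.8, beta = c(0.9, -0.9),
                     intercept = 100, sigma = 150^2)
  sc <- scenario_config(0.05, 12, baseline_capacity = 1000,
                        baseline_demand = 1000, n_sims = 500, seed = 4,
                        reference_level = 1)
  w1 <- project_waitlist(narrow, sc, init = matrix(5000))$percentiles
  w2 <- project_waitlist(wide, sc, init = matrix(5000))$percentiles
  expect_true(all(w2[, "p97.5"] - w2[, "p2.5"] >= w1[, "p97.5"] - w1[, "p2.5"]))
})

test_that("doubling the simulation count moves the median less than the reported error bound", {
  pan <- simulate_panel(study_truth(), 44, seed = 13)
  f <- varx(pan, lags = c(1, 4))
  bl <- baseline_flows(pan, 2023)
  mk <- function(n) scenario_config(0.1, 12, bl$capacity, bl$demand,
                                    n_sims = n, seed = 17, reference_level = 1)
  a <- project_waitlist(f, mk(1000))
  b <- project_waitlist(f, mk(2000))
  diff_med <- abs(a$percentiles[, "p50"] - b$percentiles[, "p50"])
  expect_true(all(diff_med < a$mc_se_median + b$mc_se_median))
})

test_that("the minimum-capacity grid search agrees with brute force on the accounting identity", {
  # demand = capacity baseline, stock 100 above the reference: cleared at the
  # horizon iff the cumulative extra throughput sum(baseline * X * t / H)
  # = 650 X reaches 100, so the smallest grid X is 0.20
  ref <- 1000
  sc <- scenario_config(0, 12, baseline_capacity = 100, baseline_demand = 100,
                        n_sims = 10, seed = 1, reference_level = ref)
  search <- find_min_capacity_increase(identity_model(), grid = seq(0, 0.25, 0.05),
                                       scenario = sc, init = matrix(ref + 100))
  # brute force: explicit recursion at every grid point
  brute <- NA_real_
  for (X in seq(0, 0.25, 0.05)) {
    pend <- ref + 100
    cleared <- FALSE
    for (t in 1:12) {
      pend <- pend + 100 - 100 * (1 + X * t / 12)
      if (pend <= ref) { cleared <- TRUE; break }
    }
    if (cleared) { brute <- X; break }
  }
  expect_equal(search$min_increase, 0.20)
  expect_equal(search$min_increase, brute)

  # a reference above the initial stock clears immediately at X = 0
  sc2 <- sc; sc2$reference_level <- 5000
  s2 <- find_min_capacity_increase(identity_model(), grid = seq(0, 0.25, 0.05),
                                   scenario = sc2, init = matrix(1000))
  expect_equal(s2$min_increase, 0)
  expect_equal(s2$table$clearance_quarter[1], 1L)

  # when nothing on the grid clears, that is reported, not raised
  sc3 <- sc; sc3$reference_level <- 10
  s3 <- find_min_capacity_increase(identity_model(), grid = c(0, 0.05),
                                   scenario = sc3, init = matrix(1000))
  expect_true(is.na(s3$min_increase))
  expect_false(any(s3$table$cleared))
})

test_that("the linear counterfactual recovers exact and hand-computed slopes", {
  # exactly linear: slope 3750/quarter
  n <- 36
  pan <- toy_panel(rep(10000, n), rep(6250, n), pending0 = 250000)
  lc <- linear_counterfactual(pan, projection_end = as.Date("2026-12-31"))
  expect_equal(lc$slope, 3750)
  expect_equal(lc$annualised_slope, 15000)
  last <- lc$trajectory$counterfactual[nrow(lc$trajectory)]
  expect_equal(last, 250000 + 3750 * 56)   # 2026 Q4 is quarter index 56
  # extrapolation exact: value at quarter index i is intercept + slope * i
  expect_equal(lc$trajectory$counterfactual,
               lc$intercept + lc$slope * seq_len(nrow(lc$trajectory)))

  # 5-point hand least squares
  p5 <- c(120, 123, 131, 133, 142)
  add5 <- rep(20, 5); rem5 <- add5 - diff(c(p5[1] - 4, p5))
  pan5 <- toy_panel(add5, rem5, pending0 = p5[1] - 4)
  expect_equal(pending_of(pan5), p5)
  lc5 <- linear_counterfactual(pan5, window_start = as.Date("2013-03-31"),
                               window_end = as.Date("2014-03-31"),
                               projection_end = as.Date("2014-03-31"))
  i <- 1:5
  slope_hand <- sum((i - mean(i)) * (p5 - mean(p5))) / sum((i - mean(i))^2)
  expect_equal(lc5$slope, slope_hand)

  expect_error(linear_counterfactual(pan5, window_start = as.Date("2013-03-31"),
                                     window_end = as.Date("2013-06-30"),
                                     projection_end = as.Date("2014-03-31")),
               "at least 3")
})

test_that("pre-shock panels reproduce the configured annual growth on average", {
  slopes <- vapply(1:40, function(sd) {
    pan <- generate_panel(synthetic_config(seed = 300 + sd))
    linear_counterfactual(pan, projection_end = as.Date("2019-12-31"))$annualised_slope
  }, 0)
  expect_lt(abs(mean(slopes) - 15000), 0.10 * 15000)
})
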