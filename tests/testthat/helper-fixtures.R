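# Shared fixtures built in code.

# Conserving single-stratum panel from explicit flow vectors.
toy_panel <- function(additions, removals, pending0,
                      start_year = 2013, start_quarter = 1,
                      elective_type = "all", hb_code = "Scotland",
                      specialty = "all") {
  n <- length(additions)
  codes <- seq(start_year * 4 + (start_quarter - 1), length.out = n)
  pending <- pending0 + cumsum(additions - removals)
  waitlist_panel(data.frame(
    quarter_end_date = quarter_end_date(codes),
    elective_type = elective_type, hb_code = hb_code, specialty = specialty,
    additions = additions, removals = removals, pending = pending,
    stringsAsFactors = FALSE
  ))
}

# Known-coefficient truth used across the simulation studies: persistent
# stock with a seasonal echo at lag 4 and near-unit pass-through of flows.
study_truth <- function() {
  varx_model(lags = c(1, 4), phi = c(0.55, 0.30), beta = c(0.8, -0.8),
             intercept = 400, sigma = 100^2)
}

# Accounting identity: pending[t] = pending[t-1] + additions[t] - removals[t].
identity_model <- function(sigma = 0) {
  varx_model(lags = 1, phi = 1, beta = c(1, -1), intercept = 0, sigma = sigma)
}

pending_of <- function(panel) waitlistr:::panel_series(panel)$pending
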