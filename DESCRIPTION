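Package: waitlistr
Title: Stock-Flow Modelling of Elective-Care Waiting Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing hospital elective-care waiting lists as a
    quarterly stock-flow system: synthetic panel generation with seasonality
    and a capacity-shock regime, readers for Public Health Scotland
    "Stage of Treatment" style open-data CSVs, descriptive comparisons of
    pre-pandemic and pandemic periods (quarterly means with seasonally
    adjusted confidence intervals, percentage changes, wait-band exceedance),
    a vector autoregressive model with exogenous inflow and outflow fitted by
    Gaussian maximum likelihood with AIC lag-set selection, Monte Carlo
    projection of waiting-list trajectories under graded capacity-increase
    scenarios with prediction intervals and minimum-capacity-to-clear search,
    and assessment of observed throughput against published recovery-plan
    targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
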