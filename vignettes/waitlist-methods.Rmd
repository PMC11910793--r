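---
title: "Modelling elective-care waiting lists as a stock-flow system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling elective-care waiting lists as a stock-flow system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waitlistr)
```

## The system and its accounting

A hospital waiting list is a stock fed and drained by two flows. In each
quarter `t`, `additions[t]` referrals join the list, `removals[t]` leave it
for any reason (treated, transferred, no longer required, died), and
`pending[t]` is the stock still waiting at the quarter's end:

```
pending[t] = pending[t-1] + additions[t] - removals[t]
```

We call `removals` the system's *capacity* in the pragmatic sense of
realised throughput, not theoretical potential. Data of this shape are
published quarterly by Public Health Scotland's "Stage of Treatment"
open dataset, stratified by elective type (outpatient vs all admitted
cases, which we call inpatient), 14 territorial health boards, and about
49 specialties. `read_panel()` ingests such CSVs through an explicit
column-mapping schema; nothing in the reader is hard-coded to one release
dialect, because the published column vocabulary changes across vintages.

On real data the accounting identity holds only approximately (published
extracts carry revisions and documented quality issues), so readers compute
the reconciliation residual per quarter and *store* it — counts are never
"corrected". On synthetic data the identity is enforced exactly: flows are
drawn as real numbers, rounded half-to-even, and the stock is recomputed
from the rounded flows, so there is no drift between stock and flows.

## What the synthetic generator emulates

`generate_panel()` produces panels with the statistical structure the
analysis assumes:

* a linear pre-shock trend in the stock, driven by a persistent gap between
  mean inflow and outflow;
* additive quarter-of-year seasonality in both flows (additive rather than
  multiplicative, matching the additive linear model fitted downstream);
* a sudden collapse in throughput with slow partial recovery: from the
  shock quarter, the outflow baseline is multiplied by
  `1 - depth * max(0, 1 - rate * quarters_since_shock)`;
* Gaussian flow noise, floored at zero (the shortfall is logged, not
  redistributed — at realistic scales it is negligible).

The defaults emulate Scotland's national aggregate over 2013--2023: 44
quarters, initial stock 254,612, net inflow 3,750/quarter (about 15,000
referrals a year, the pre-pandemic growth), shock of depth 0.67 in quarter
30 (the April--June 2020 lockdown quarter saw throughput fall by about
two-thirds), and a recovery rate of 0.055 per quarter, leaving throughput
roughly 15% below baseline after four years, as observed. Seasonal
amplitudes of order 1--3% of the baselines and flow noise of 5--6 thousand
were chosen once as values a practitioner would call realistic for series
of this magnitude.

One divergence is deliberate and worth understanding: with demand held at
its baseline (the default — the shock applies to removals only), a depth-0.67
collapse recovering slowly implies a much larger cumulative stock build-up
than Scotland actually recorded, because real referral *demand* also fell
during lockdown and recovered gradually. The generator therefore matches
the capacity regime and the pre-shock trend, not the absolute pandemic-era
stock level. Tests that depend on the stock level use the generator's own
trajectory, never the national figures. An `additions_shock_multiplier` is
available for users who want a transient demand dip.

Wait-duration tables (`generate_wait_bands()`) use exact cohort
bookkeeping: a quarter is 13 weeks, so a cohort that entered in quarter `t`
has waited between `13k` and `13(k+1)` weeks at the end of quarter `t+k`,
and its band (0--12, 13--52, >52 weeks by default) follows deterministically
from its age. The aging profile's per-band resolved share (one minus its
row sum) sets the relative propensity of each band's referrals to be
removed; the panel's removals are then apportioned across cohorts by
largest-remainder integer allocation, capped at cohort size. Band counts
therefore partition the pending stock (ongoing) and the removals
(completed) exactly, by construction. We deliberately do *not* move cohorts
by random fractions: age, not chance, determines how long someone has
waited, and the fractional-transition reading would make simple cohort
arithmetic (e.g. "with no resolution, everything added up to `n-4` quarters
ago is waiting over a year") only approximately true.

What passing tests on these panels do **not** show: real referral data have
demand shocks, revisions, specialty-level heterogeneity in aging, and
non-Gaussian flow noise. The generator makes the pipeline testable, not the
data realistic in every respect.

## Descriptive comparisons

`quarterly_mean_ci()` reports the arithmetic mean of a year's four
quarterly values with a 95% interval. Quarterly counts are strongly
seasonal, and a naive t-interval on four raw values conflates seasonality
with sampling noise. The default scheme therefore estimates quarter-of-year
effects by regressing the full available series on a linear trend plus
quarter dummies (the trend term stops secular growth leaking into the
seasonal offsets), centres the offsets, adjusts the year's four values, and
forms `mean ± t(0.975, 3) · sd(adjusted)/2`. The exact construction used in
published national tables is not documented publicly, so the scheme is a
selectable strategy (`scheme = "raw"` gives the plain t-interval) and the
choice is recorded in the output. A constant year yields a zero-width
interval under either scheme.

`percent_change()`, `exceedance()` (no interpolation inside bands — the
threshold must sit on a band edge), and `stratified_table()` (per-stratum
means, changes and threshold flags, e.g. ">100% increase" or ">60% waiting
over 12 weeks") complete the descriptive layer. Reporting follows the
conventions of the field: thousands to one decimal in tables, whole
percentages in prose; raw values are always retained.

## The VARX model

The core model treats the pending stock as endogenous and the two flows as
exogenous inputs:

$$y_t = c + \sum_{l \in L} \Phi_l\, y_{t-l} + B x_t + \varepsilon_t,
  \qquad \varepsilon_t \sim N(0, \Sigma)$$

with $x_t$ the contemporaneous additions and removals and
$L \subseteq \{1,2,3,4\}$ — a maximum order of four captures seasonal
dependence in quarterly data. The default endogenous block is a single
aggregate pending series; a two-series inpatient/outpatient block can be
fitted jointly (`endog = c("inpatient", "outpatient")`), since the two
streams are reported and projected separately. Which block was used is
recorded on the fit. We deliberately do not give the flows their own
dynamics: in projection they are policy inputs (a demand assumption and a
capacity ramp), not behaviours to extrapolate.

Estimation choices, all of which matter for comparability:

* **Conditional Gaussian likelihood.** The first `max(L)` quarters are
  conditioned on, not modelled. For this linear-Gaussian model the ML
  coefficients coincide with least squares per equation and $\Sigma$ is the
  residual covariance with divisor $n$. Exact-likelihood refinements are
  immaterial at 40-odd observations for a model-selection purpose and would
  cost determinism and transparency.
* **Parameter count.** `k` counts every free coefficient *plus* the
  $m(m+1)/2$ free elements of $\Sigma$, and `AIC = 2k - 2 logLik`. Any
  reimplementation must use the same convention for the comparison table to
  match.
* **Aligned samples.** `select_varx()` fits all candidate lag sets —
  `{1}`, `{4}`, `{1,4}`, `{1,2,3,4}` — on a common estimation sample
  (presample 4), so AICs compare identical response rows. Ties break toward
  fewer parameters, then the smaller maximum lag.
* **Levels, not differences.** The stock is modelled in levels; the
  exogenous flows absorb the trend.

Degenerate inputs are handled explicitly: rank-deficient designs are
rejected naming the collinear columns (the commonest cause: additions and
removals identical), and a perfect fit with exactly zero residual variance
yields an infinite log-likelihood and a degenerate AIC rather than a
misleading finite number. Fitting accounting-identity data (where a lag-1
model reproduces the stock exactly up to rounding) is such a degenerate
case: the likelihood is driven by roundoff, not information. AIC selection
is meaningful only on data with genuine innovation noise in the stock
equation; `simulate_panel()` exists precisely to make such data, with known
coefficients, for the simulation studies.

## Monte Carlo projection

`project_waitlist()` iterates the fitted equation forward over a horizon of
`H` quarters (default 12 — a three-year projection matching the recovery
plan's timeline) with additions fixed at `baseline_demand ×
demand_multiplier` and removals on the linear ramp
`baseline × (1 + X t / H)` — a uniform rate of increase accumulating to the
fraction `X` by the horizon's end, so `X = 0.20` over three years is 6.67
percentage points a year. Innovations are Gaussian draws from the fitted
$\Sigma$ by default (the ML-consistent choice); a residual bootstrap is
available by configuration and the choice is recorded. The stock is floored
at zero; flows are not forced to integers during simulation, since rounding
is immaterial at aggregate scale.

Per quarter, the 2.5th, 50th and 97.5th percentiles over the (default
1000) simulations form the median trajectory and 95% prediction interval.
Clearance — returning to the pre-pandemic stock level, by default the
end-2019 snapshot (for synthetic runs, the generator's pre-shock endpoint)
— is judged on the median trajectory, matching the headline framing of
"the capacity must increase by at least X%"; a conservative variant judges
on the 97.5th percentile (`clearance_on = "upper"`). A Monte Carlo error
bound for the median (three times the asymptotic standard error of a sample
median) is reported alongside, and doubling the simulation count moves the
median by less than the sum of the two runs' bounds.

`find_min_capacity_increase()` evaluates a grid of increases (default 0 to
25% in five-point steps) with **common random numbers**: one innovation
array is drawn from the scenario seed and shared by every grid point, so
scenario contrasts are not confounded with simulation noise. Because
capacity enters with a negative coefficient and the autoregressive
coefficients are non-negative in this domain, each simulated path — and
hence each quarter's median and the median peak — is monotone non-increasing
in the capacity increase under common draws; the tests assert this. If no
grid value clears the backlog, the result says so; it is not an error.

`linear_counterfactual()` provides the no-pandemic comparison: an ordinary
least-squares line through the pre-pandemic window (2013 Q1 to 2019 Q4 by
default), extrapolated forward.

One published figure deserves a caveat: a 20% increase over three years on
a quarterly capacity baseline `C` adds `C × 4 × 0.20 / 3` cases a year
under the linear ramp, and no capacity baseline printed in the national
tables makes that expression equal the widely quoted "additional 32,302
cases per year". The package reports extra-cases-per-year from its own
declared baseline and leaves the discrepancy visible rather than matching
the printed figure.

## Recovery-plan assessment

The plan's published anchors — pre-pandemic reference levels of 67,500
inpatient and 350,000 outpatient cases per quarter; targets of 74,375 and
364,500 for April--June 2022; envisaged per-quarter increases of 7,625 and
17,071 through the end of 2023 — define the default target trajectory
(linear between anchors; overridable, since the plan's exact quarterly
profile is not reprinted anywhere authoritative). `quarter_shortfall()` is
`100 (target - observed)/target`, whole-percent reporting, surpluses
negative and never clamped. The published "per quarter increase … (seven
quarters)" is ambiguous between a regression slope and an endpoint
difference over six gaps; `mean_quarterly_increase()` implements both, the
default is the slope, both agree exactly on linear series, and the
estimator used is recorded in the output.

## Problem sizes and numerical conventions

The simulation studies in the test suite and acceptance script run at the
scale the analysis itself uses: panels of 44 quarters (40 estimation rows
after the presample), flow noise sd 100 in the known-truth studies, 500
replicates for coefficient recovery, 200 for lag-set selection, and 1000
simulations per scenario over 12 quarters across a six-point capacity grid.
Quantiles use the default type-7 estimator throughout, so interval
comparisons across runs are at a fixed estimator. All randomness flows
through explicit integer seeds, and every seeded routine restores the
caller's RNG state.

## Known limitations

* Demand over the projection horizon is a fixed assumption (with a
  sensitivity grid), not a forecast; external shocks and policy changes are
  out of scope.
* Inpatient and outpatient streams are modelled independently; no
  interaction between outpatient throughput and inpatient demand is
  estimated.
* No demographic structure (age, deprivation) — the unit is the quarterly
  aggregate, as in the source data.
* No statistical testing of between-period differences; the descriptive
  layer reports means, intervals and changes only.
* The wait-band generator's initial stock is treated as a single cohort
  entering just before the first quarter; if the age composition of the
  initial stock matters, start the panel earlier.
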