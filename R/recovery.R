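#' Recovery-plan capacity targets
#'
#' Default quarterly elective-capacity targets from the NHS Recovery Plan
#' 2021--2026 anchors: pre-pandemic reference levels of 67,500 inpatient
#' and 350,000 outpatient cases per quarter; a target of 74,375 inpatients
#' and 364,500 outpatients for the quarter April--June 2022; and envisaged
#' per-quarter increases of 7,625 (inpatients) and 17,071 (outpatients)
#' through the last quarter of 2023. Between the published anchors the
#' trajectory is linear with those increments. Supply your own data frame
#' to override (columns `quarter_end_date`, `elective_type`, `target`).
#'
#' @param elective_type `"inpatient"`, `"outpatient"`, or both (default).
#' @return data frame of quarterly targets for 2022 Q2 through 2023 Q4,
#'   with the pre-pandemic reference levels and envisaged per-quarter
#'   increases in attributes `"reference_level"` and `"envisaged_increase"`.
#' @export
recovery_targets <- function(elective_type = c("inpatient", "outpatient")) {
  elective_type <- match.arg(elective_type, several.ok = TRUE)
  codes <- qcode(2022, 2):qcode(2023, 4)           # seven quarters
  anchors <- list(inpatient = 74375, outpatient = 364500)
  increments <- list(inpatient = 7625, outpatient = 17071)
  refs <- list(inpatient = 67500, outpatient = 350000)
  rows <- lapply(elective_type, function(ty) {
    data.frame(
      quarter_end_date = quarter_end_date(codes),
      elective_type = ty,
      target = anchors[[ty]] + increments[[ty]] * (seq_along(codes) - 1),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_level") <- unlist(refs[elective_type])
  attr(out, "envisaged_increase") <- unlist(increments[elective_type])
  out
}

#' Percentage shortfall of observed capacity against a quarterly target
#'
#' `100 * (target - observed) / target`, reported as a whole percentage. A
#' surplus (observed above target) yields a negative value, reported as
#' such, never clamped.
#'
#' @param observed,target quarterly counts; `target` must be positive.
#' @param digits reporting precision (default whole percent; `NULL` for
#'   unrounded).
#' @return percentage shortfall.
#' @export
quarter_shortfall <- function(observed, target, digits = 0) {
  if (any(target <= 0)) stop("target must be positive")
  sf <- 100 * (target - observed) / target
  if (is.null(digits)) sf else round(sf, digits)
}

#' Mean quarterly increase in capacity over a window
#'
#' Default estimator is the least-squares slope of observed capacity on the
#' quarter index. The alternative, `method = "endpoint"`, divides the
#' difference between the last and first quarter by the number of gaps.
#' Both agree exactly on a linear series; the estimator used is recorded in
#' the `"method"` attribute of the result.
#'
#' @param observed numeric vector of quarterly capacity (>= 2 quarters).
#' @param method `"slope"` (default) or `"endpoint"`.
#' @return estimated increase per quarter (counts/quarter).
#' @export
mean_quarterly_increase <- function(observed, method = c("slope", "endpoint")) {
  method <- match.arg(method)
  if (length(observed) < 2) stop("at least two quarters are required")
  est <- if (method == "slope") {
    idx <- seq_along(observed)
    unname(stats::coef(stats::lm(observed ~ idx))[2])
  } else {
    (observed[length(observed)] - observed[1]) / (length(observed) - 1)
  }
  structure(est, method = method)
}

#' Percentage shortfall of the observed capacity increase
#'
#' `100 * (envisaged - observed) / envisaged`, whole-percent reporting.
#'
#' @param observed_increase achieved increase per quarter.
#' @param envisaged_increase planned increase per quarter (> 0).
#' @param digits reporting precision (default whole percent).
#' @return percentage shortfall.
#' @export
increase_shortfall <- function(observed_increase, envisaged_increase,
                               digits = 0) {
  if (any(envisaged_increase <= 0)) stop("envisaged increase must be positive")
  sf <- 100 * (envisaged_increase - as.numeric(observed_increase)) /
    envisaged_increase
  if (is.null(digits)) sf else round(sf, digits)
}

#' Assess observed capacity against recovery-plan targets
#'
#' Produces the tidy comparison behind a two-panel recovery figure: per
#' quarter, the observed removals of each elective type against its target
#' with the percentage shortfall; and, per type, the mean quarterly
#' capacity increase achieved over the window against the envisaged
#' increase, with its shortfall. All percentages recompute exactly from the
#' stored raw counts.
#'
#' @param panel `waitlist_panel` containing the observed series (strata
#'   with matching `elective_type`).
#' @param targets target data frame from [recovery_targets()] (or the same
#'   shape).
#' @param method estimator passed to [mean_quarterly_increase()].
#' @return a `recovery_assessment` list: `$quarters` (per-quarter observed,
#'   target, shortfall %), `$increase` (per-type observed and envisaged
#'   increase and shortfall %), `$method`.
#' @export
recovery_assessment <- function(panel, targets = recovery_targets(),
                                method = c("slope", "endpoint")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "waitlist_panel"))
  envisaged <- attr(targets, "envisaged_increase")
  types <- unique(targets$elective_type)
  qrows <- list()
  irows <- list()
  for (ty in types) {
    tt <- targets[targets$elective_type == ty, , drop = FALSE]
    tt <- tt[order(tt$quarter_end_date), , drop = FALSE]
    sub <- panel_subset(panel, elective_type = ty)
    s <- panel_series(sub)
    idx <- match(date_qcode(tt$quarter_end_date), s$code)
    if (anyNA(idx)) {
      stop("panel lacks observed quarters for ", ty, ": ",
           paste(utils::head(format(tt$quarter_end_date[is.na(idx)]), 3),
                 collapse = ", "))
    }
    obs <- s$removals[idx]
    qrows[[ty]] <- data.frame(
      quarter_end_date = tt$quarter_end_date,
      elective_type = ty,
      observed = obs,
      target = tt$target,
      shortfall_pct = quarter_shortfall(obs, tt$target),
      stringsAsFactors = FALSE
    )
    inc <- mean_quarterly_increase(obs, method = method)
    env_ty <- if (!is.null(envisaged)) unname(envisaged[ty]) else NA_real_
    irows[[ty]] <- data.frame(
      elective_type = ty,
      observed_increase = as.numeric(inc),
      envisaged_increase = env_ty,
      shortfall_pct = if (is.na(env_ty)) NA_real_ else
        increase_shortfall(inc, env_ty),
      stringsAsFactors = FALSE
    )
  }
  out <- list(quarters = do.call(rbind, c(qrows, list(make.row.names = FALSE))),
              increase = do.call(rbind, c(irows, list(make.row.names = FALSE))),
              method = method)
  class(out) <- "recovery_assessment"
  out
}

#' @export
print.recovery_assessment <- function(x, ...) {
  cat("Observed capacity vs recovery-plan targets (", x$method,
      " estimator for the quarterly increase):\n\n", sep = "")
  print(x$quarters, row.names = FALSE)
  cat("\nMean quarterly capacity increase:\n")
  print(x$increase, row.names = FALSE)
  invisible(x)
}
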