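#' Construct a quarterly waiting-list panel
#'
#' A `waitlist_panel` is a data frame with one row per quarter and stratum,
#' holding the stock-flow accounting of a waiting list: `additions[t]`
#' referrals joined the list during quarter `t`, `removals[t]` left it for
#' any reason (the realised throughput, often called "capacity"), and
#' `pending[t]` is the stock still waiting at the end of the quarter.
#'
#' Strata are combinations of elective type (`"inpatient"`, `"outpatient"`,
#' or `"all"`), health-board code (a territorial board or `"Scotland"`), and
#' specialty code (or `"all"`). Validation enforces non-negative integer
#' counts and strictly increasing, gap-free quarters within each stratum.
#'
#' Stock-flow conservation, `pending[t] - pending[t-1] = additions[t] -
#' removals[t]`, holds exactly for synthetic panels. For observed data the
#' reconciliation residual is computed per quarter and stored in the
#' `"conservation"` attribute; it is reported, never applied as a correction.
#'
#' @param df data frame with columns `quarter_end_date` (Date or parseable),
#'   `elective_type`, `hb_code`, `specialty`, `additions`, `removals`,
#'   `pending`.
#' @param conserve if `TRUE`, any non-zero conservation residual is an error
#'   (the contract for generated data); if `FALSE` residuals are recorded.
#' @return the validated panel, classed `waitlist_panel`.
#' @seealso [generate_panel()], [read_panel()], [panel_conservation()]
#' @export
waitlist_panel <- function(df, conserve = FALSE) {
  req <- c("quarter_end_date", "elective_type", "hb_code", "specialty",
           "additions", "removals", "pending")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("panel is missing required columns: ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$quarter_end_date <- if (inherits(df$quarter_end_date, "Date")) {
    df$quarter_end_date
  } else {
    as.Date(as.character(df$quarter_end_date), optional = TRUE)
  }
  if (anyNA(df$quarter_end_date)) {
    stop("unparseable quarter_end_date in rows: ",
         paste(utils::head(which(is.na(df$quarter_end_date)), 5), collapse = ", "))
  }
  for (col in c("additions", "removals", "pending")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("column '", col, "' must be numeric and complete")
    }
    if (any(v < 0)) {
      stop("negative counts in '", col, "' (rows ",
           paste(utils::head(which(v < 0), 5), collapse = ", "), ")")
    }
    if (any(abs(v - round(v)) > 1e-8)) {
      stop("fractional counts in '", col, "' (rows ",
           paste(utils::head(which(abs(v - round(v)) > 1e-8), 5), collapse = ", "),
           "); counts of referrals must be integers")
    }
    df[[col]] <- as.numeric(round(v))
  }

  key <- panel_stratum_key(df)
  code <- date_qcode(df$quarter_end_date)
  dup <- duplicated(paste(key, code))
  if (any(dup)) {
    stop("duplicate (quarter, stratum) rows, e.g. ",
         quarter_label(code[dup][1]), " / ", key[dup][1])
  }
  ord <- order(key, code)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  code <- code[ord]
  key <- key[ord]

  resid <- rep(NA_real_, nrow(df))
  for (k in unique(key)) {
    i <- which(key == k)
    ci <- code[i]
    if (length(i) > 1 && any(diff(ci) != 1L)) {
      gap <- i[which(diff(ci) != 1L)[1]]
      stop("quarters must be consecutive within stratum '", k,
           "': gap after ", quarter_label(code[gap]))
    }
    if (length(i) > 1) {
      resid[i[-1]] <- diff(df$pending[i]) -
        (df$additions[i[-1]] - df$removals[i[-1]])
    }
  }
  if (conserve && any(abs(resid) > 0, na.rm = TRUE)) {
    bad <- which(abs(resid) > 0)[1]
    stop("stock-flow conservation violated at ",
         quarter_label(code[bad]), " (stratum ", key[bad],
         "): residual ", resid[bad])
  }
  attr(df, "conservation") <- data.frame(
    quarter_end_date = df$quarter_end_date,
    stratum = key,
    residual = resid,
    stringsAsFactors = FALSE
  )
  class(df) <- c("waitlist_panel", "data.frame")
  df
}

panel_stratum_key <- function(df) {
  paste(df$elective_type, df$hb_code, df$specialty, sep = "|")
}

#' Conservation residuals of a panel
#'
#' @param panel a `waitlist_panel`.
#' @return data frame of per-quarter reconciliation residuals
#'   `pending[t] - pending[t-1] - additions[t] + removals[t]` (NA for the
#'   first quarter of each stratum, where no previous stock is observed).
#' @export
panel_conservation <- function(panel) {
  stopifnot(inherits(panel, "waitlist_panel"))
  attr(panel, "conservation")
}

#' Restrict a panel to one stratum
#'
#' @param panel a `waitlist_panel`.
#' @param elective_type,hb_code,specialty stratum selectors; `NULL` keeps all.
#' @return a `waitlist_panel` containing the matching rows.
#' @export
panel_subset <- function(panel, elective_type = NULL, hb_code = NULL,
                         specialty = NULL) {
  stopifnot(inherits(panel, "waitlist_panel"))
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(elective_type)) keep <- keep & panel$elective_type %in% elective_type
  if (!is.null(hb_code)) keep <- keep & panel$hb_code %in% hb_code
  if (!is.null(specialty)) keep <- keep & panel$specialty %in% specialty
  if (!any(keep)) stop("no rows match the requested stratum")
  waitlist_panel(as.data.frame(panel)[keep, , drop = FALSE])
}

#' Aggregate a panel across strata
#'
#' Sums the additive measures (additions, removals, pending) over the strata
#' collapsed out. Conservation is preserved by additivity.
#'
#' @param panel a `waitlist_panel`.
#' @param by character vector of stratum keys to keep, a subset of
#'   `c("elective_type", "hb_code", "specialty")`; keys not kept are
#'   collapsed to `"all"` (health board to `"Scotland"`).
#' @return aggregated `waitlist_panel`.
#' @export
aggregate_panel <- function(panel, by = character()) {
  stopifnot(inherits(panel, "waitlist_panel"))
  df <- as.data.frame(panel)
  if (!("elective_type" %in% by)) df$elective_type <- "all"
  if (!("hb_code" %in% by)) df$hb_code <- "Scotland"
  if (!("specialty" %in% by)) df$specialty <- "all"
  agg <- stats::aggregate(
    df[c("additions", "removals", "pending")],
    by = df[c("quarter_end_date", "elective_type", "hb_code", "specialty")],
    FUN = sum
  )
  waitlist_panel(agg)
}

#' @export
print.waitlist_panel <- function(x, ...) {
  key <- unique(panel_stratum_key(x))
  code <- date_qcode(x$quarter_end_date)
  cat("Waiting-list panel: ", length(unique(code)), " quarters (",
      quarter_label(min(code)), " to ", quarter_label(max(code)), "), ",
      length(key), " stratum", if (length(key) != 1) "s" else "", "\n", sep = "")
  res <- attr(x, "conservation")$residual
  if (all(is.na(res) | res == 0)) {
    cat("Stock-flow conservation: exact\n")
  } else {
    cat("Stock-flow conservation: max |residual| ",
        max(abs(res), na.rm = TRUE), "\n", sep = "")
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Extract one stratum's series as vectors
#'
#' Internal convenience: returns quarters (codes), additions, removals,
#' pending for a single-stratum panel, ordered in time.
#' @noRd
panel_series <- function(panel) {
  key <- unique(panel_stratum_key(panel))
  if (length(key) != 1) {
    stop("panel has ", length(key), " strata; subset or aggregate to one ",
         "(see panel_subset(), aggregate_panel())")
  }
  code <- date_qcode(panel$quarter_end_date)
  ord <- order(code)
  list(
    code = code[ord],
    additions = panel$additions[ord],
    removals = panel$removals[ord],
    pending = panel$pending[ord]
  )
}
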