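#' Calendar-quarter utilities
#'
#' Quarters are represented internally by an integer code `year * 4 +
#' (quarter - 1)`, which makes sequences, gaps and lags trivial to reason
#' about. User-facing representations are labels such as `"2019 Q4"` and
#' quarter-end `Date`s (the snapshot convention: "end of 2019" is the
#' 2019 Q4 row, i.e. December 31, 2019).
#'
#' @param year integer year(s).
#' @param quarter quarter-of-year, 1--4.
#' @name quarters
NULL

qcode <- function(year, quarter) {
  stopifnot(all(quarter %in% 1:4))
  as.integer(year) * 4L + (as.integer(quarter) - 1L)
}

qcode_year <- function(code) code %/% 4L

qcode_quarter <- function(code) code %% 4L + 1L

#' @rdname quarters
#' @param code integer quarter code as returned by internal helpers.
#' @return `quarter_label()` returns labels like `"2013 Q1"`;
#'   `quarter_end_date()` the last calendar day of the quarter.
#' @export
quarter_label <- function(code) {
  sprintf("%d Q%d", qcode_year(code), qcode_quarter(code))
}

#' @rdname quarters
#' @export
quarter_end_date <- function(code) {
  y <- qcode_year(code)
  q <- qcode_quarter(code)
  # last day of month 3q: first day of next month minus one
  nxt_m <- q * 3 + 1
  nxt_y <- ifelse(nxt_m > 12, y + 1, y)
  nxt_m <- ifelse(nxt_m > 12, 1, nxt_m)
  as.Date(sprintf("%d-%02d-01", nxt_y, nxt_m)) - 1
}

#' Quarter code of a date (the quarter containing it)
#' @noRd
date_qcode <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  qcode(y, (m - 1L) %/% 3L + 1L)
}

#' Sequence of quarter codes
#' @noRd
qcode_seq <- function(start_year, start_quarter, n) {
  qcode(start_year, start_quarter) + seq_len(n) - 1L
}
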