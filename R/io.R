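#' Column-mapping schema for waiting-list CSVs
#'
#' Open-data releases name their columns differently across publishers and
#' vintages, so the readers take an explicit mapping from canonical field
#' names to source column names rather than hard-coding one dialect. The
#' default is the canonical dialect this package writes. For Public Health
#' Scotland "Stage of Treatment" extracts, supply the release's column
#' names, e.g. `phs_schema(quarter_end_date = "QuarterEnding", hb_code =
#' "HBT", specialty = "Specialty", additions = "Additions", removals =
#' "Removals", pending = "NumberWaiting")`.
#'
#' @param ... canonical = source column name pairs overriding the defaults.
#' @param date_format passed to [as.Date()] when parsing quarter-end dates
#'   (`NULL` lets `as.Date` infer ISO formats).
#' @return a named list usable as the `schema` argument of [read_panel()]
#'   and [read_wait_bands()].
#' @export
phs_schema <- function(..., date_format = NULL) {
  schema <- list(
    quarter_end_date = "quarter_end_date",
    elective_type = "elective_type",
    hb_code = "hb_code",
    specialty = "specialty",
    additions = "additions",
    removals = "removals",
    pending = "pending",
    kind = "kind",
    band_lower = "band_lower",
    band_upper = "band_upper",
    count = "count"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(schema))
  if (length(bad)) stop("unknown schema fields: ", paste(bad, collapse = ", "))
  schema[names(over)] <- over
  attr(schema, "date_format") <- date_format
  schema
}

read_mapped <- function(paths, schema, fields) {
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("file not found: ", paste(missing_files, collapse = ", "))
  }
  parts <- lapply(paths, function(p) {
    raw <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    src <- unlist(schema[fields])
    miss <- src[!(src %in% names(raw))]
    if (length(miss)) {
      stop("file '", p, "' is missing mapped columns: ",
           paste(miss, collapse = ", "))
    }
    out <- raw[, src, drop = FALSE]
    names(out) <- fields
    out
  })
  df <- do.call(rbind, parts)
  fmt <- attr(schema, "date_format")
  raw_dates <- df$quarter_end_date
  df$quarter_end_date <- if (is.null(fmt)) {
    as.Date(as.character(raw_dates), optional = TRUE)
  } else {
    as.Date(as.character(raw_dates), format = fmt)
  }
  if (anyNA(df$quarter_end_date)) {
    bad <- which(is.na(df$quarter_end_date))
    stop("unparseable quarter-end dates, e.g. row ", bad[1], ": '",
         raw_dates[bad[1]], "'")
  }
  df
}

#' Read a waiting-list panel from CSV
#'
#' Validates on ingest: missing mapped columns, unparseable dates, duplicate
#' (quarter, stratum) rows, gaps in the quarterly sequence, and negative or
#' fractional counts are all rejected with row-level diagnostics. Stock-flow
#' reconciliation residuals are computed per stratum and stored on the
#' returned panel (see [panel_conservation()]); residuals beyond
#' `conservation_tol` of the pending stock raise a warning, but counts are
#' never altered.
#'
#' @param paths one or more CSV files (rows are concatenated).
#' @param schema column mapping from [phs_schema()].
#' @param conservation_tol warning threshold for `|residual| / pending`
#'   (default 1%; published quarterly extracts carry documented data-quality
#'   revisions, so small residuals are expected in real data).
#' @return a `waitlist_panel`.
#' @export
read_panel <- function(paths, schema = phs_schema(), conservation_tol = 0.01) {
  fields <- c("quarter_end_date", "elective_type", "hb_code", "specialty",
              "additions", "removals", "pending")
  df <- read_mapped(paths, schema, fields)
  panel <- waitlist_panel(df)
  res <- panel_conservation(panel)
  rel <- abs(res$residual) / pmax(panel$pending, 1)
  bad <- which(!is.na(rel) & rel > conservation_tol)
  if (length(bad)) {
    warning("stock-flow reconciliation residual above ",
            100 * conservation_tol, "% of pending in ", length(bad),
            " quarter(s), e.g. ",
            quarter_label(date_qcode(res$quarter_end_date[bad[1]])),
            " (stratum ", res$stratum[bad[1]], ", residual ",
            res$residual[bad[1]], "); residuals are recorded, not corrected")
  }
  panel
}

#' Write a panel to canonical CSV
#'
#' Fixed column order `quarter_end_date, elective_type, hb_code, specialty,
#' additions, removals, pending`; round-trips through [read_panel()]
#' identically. If the panel carries a generator configuration (see
#' [generate_panel()]), a JSON sidecar `<path>.config.json` recording every
#' parameter and the seed is written alongside.
#'
#' @param panel a `waitlist_panel`.
#' @param path output CSV path.
#' @param sidecar write the generator-config sidecar when available.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sidecar = TRUE) {
  stopifnot(inherits(panel, "waitlist_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  cfg <- attr(panel, "config")
  if (sidecar && !is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a wait-duration band table from CSV
#'
#' Band structure is validated (non-negative counts, ordered contiguous
#' bands, final band open-ended). If `panel` is supplied, the per-quarter
#' band sums are reconciled against the matching panel totals (pending for
#' ongoing tables, removals for completed): residuals are recorded in the
#' `"partition_residuals"` attribute and warned about beyond `tolerance`,
#' never corrected.
#'
#' @param paths one or more CSV files.
#' @param schema column mapping from [phs_schema()].
#' @param panel optional `waitlist_panel` to reconcile against.
#' @param tolerance absolute residual (counts) tolerated without warning
#'   when reconciling against `panel`; 0 for synthetic data.
#' @return a `wait_band_table`.
#' @export
read_wait_bands <- function(paths, schema = phs_schema(), panel = NULL,
                            tolerance = 0) {
  fields <- c("quarter_end_date", "elective_type", "hb_code", "specialty",
              "kind", "band_lower", "band_upper", "count")
  df <- read_mapped(paths, schema, fields)
  df$band_upper[df$band_upper %in% c("Inf", "")] <- Inf
  df$band_lower <- as.numeric(df$band_lower)
  df$band_upper <- as.numeric(df$band_upper)
  if (any(df$count < 0)) stop("negative band counts")
  if (any(abs(df$count - round(df$count)) > 1e-8)) {
    stop("fractional band counts; counts of referrals must be integers")
  }
  if (!all(df$kind %in% c("ongoing", "completed"))) {
    stop("kind must be 'ongoing' or 'completed'")
  }
  key <- paste(df$quarter_end_date, df$elective_type, df$hb_code,
               df$specialty, df$kind)
  for (k in unique(key)) {
    b <- df[key == k, , drop = FALSE]
    b <- b[order(b$band_lower), , drop = FALSE]
    if (b$band_lower[1] != 0 || !is.infinite(b$band_upper[nrow(b)]) ||
        (nrow(b) > 1 && any(b$band_lower[-1] != b$band_upper[-nrow(b)] + 1))) {
      stop("bands are not ordered, contiguous and exhaustive for ", k)
    }
  }
  class(df) <- c("wait_band_table", "data.frame")
  if (!is.null(panel)) df <- validate_band_table(df, panel, tolerance = tolerance)
  df
}

#' Write a band table to canonical CSV
#' @param bands a `wait_band_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_wait_bands <- function(bands, path) {
  stopifnot(inherits(bands, "wait_band_table"))
  utils::write.csv(as.data.frame(bands), path, row.names = FALSE)
  invisible(path)
}

#' Reconcile band sums against panel totals
#'
#' For each quarter and stratum, compares the sum over bands with the
#' panel's pending total (ongoing) or removals total (completed). Residuals
#' are attached to the returned table as `"partition_residuals"`; residuals
#' above `tolerance` raise a warning naming the first offending quarter.
#'
#' @param bands a `wait_band_table`.
#' @param panel the matching `waitlist_panel`.
#' @param tolerance maximum absolute residual not warned about.
#' @return `bands`, invisibly, with the residual attribute set.
#' @export
validate_band_table <- function(bands, panel, tolerance = 0) {
  pdf <- as.data.frame(panel)
  bdf <- as.data.frame(bands)
  sums <- stats::aggregate(
    bdf["count"],
    by = bdf[c("quarter_end_date", "elective_type", "hb_code", "specialty",
               "kind")],
    FUN = sum
  )
  m <- merge(sums, pdf,
             by = c("quarter_end_date", "elective_type", "hb_code", "specialty"))
  if (nrow(m) < nrow(sums)) {
    warning("band table has ", nrow(sums) - nrow(m),
            " quarter/stratum cells with no matching panel row")
  }
  target <- ifelse(m$kind == "ongoing", m$pending, m$removals)
  m$residual <- m$count - target
  bad <- which(abs(m$residual) > tolerance)
  if (length(bad)) {
    warning("band counts do not partition the panel total in ", length(bad),
            " cell(s), e.g. ",
            quarter_label(date_qcode(m$quarter_end_date[bad[1]])), " (",
            m$kind[bad[1]], "): bands sum to ", m$count[bad[1]],
            " against a panel total of ", target[bad[1]],
            "; residual recorded, not corrected")
  }
  attr(bands, "partition_residuals") <-
    m[c("quarter_end_date", "elective_type", "hb_code", "specialty", "kind",
        "residual")]
  invisible(bands)
}
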