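# Balanced unit x time panel of strictly positive densities. Units are kept
# sorted lexicographically (radix order, locale-independent) so every
# downstream ordering rule starts from a deterministic state.

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "logtclub_error")))
}

#' Construct a balanced density panel
#'
#' Wraps a numeric unit-by-year matrix of health-worker densities (persons per
#' 10,000 population) into a validated `conv_panel` object, the container all
#' convergence operations consume. Units are sorted lexicographically.
#'
#' @param values Numeric matrix, one row per unit, one column per year.
#' @param unit_ids Character vector of unit identifiers (defaults to row names).
#' @param years Integer vector of years (defaults to column names). Must be
#'   strictly increasing and consecutive (annual data).
#' @return An object of class `conv_panel` with fields `values` (matrix with
#'   unit/year dimnames), `unit_ids` and `years`.
#' @examples
#' p <- panel(matrix(c(2, 4, 3, 6), 2, 2), c("b", "a"), 1990:1991)
#' p$unit_ids  # sorted: "a", "b"
#' @export
panel <- function(values, unit_ids = rownames(values), years = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(unit_ids)) .err("panel requires unit identifiers", "logtclub_invalid_panel")
  if (is.null(years)) .err("panel requires years", "logtclub_invalid_panel")
  unit_ids <- as.character(unit_ids)
  years <- as.integer(as.numeric(years))
  if (length(unit_ids) != nrow(values) || length(years) != ncol(values))
    .err("dimensions of values do not match unit_ids/years", "logtclub_invalid_panel")
  ord <- order(unit_ids, method = "radix")
  values <- values[ord, , drop = FALSE]
  unit_ids <- unit_ids[ord]
  dimnames(values) <- list(unit_ids, years)
  p <- structure(list(values = values, unit_ids = unit_ids, years = years),
                 class = "conv_panel")
  validate_panel(p)
}

#' Validate panel invariants
#'
#' Checks balance (no missing cells), strict positivity, uniqueness of unit
#' ids, and that years are strictly increasing and consecutive.
#'
#' @param p A `conv_panel` object.
#' @return `p`, invisibly unchanged, if valid; otherwise a classed error
#'   (`logtclub_unbalanced_panel`, `logtclub_domain_error`,
#'   `logtclub_invalid_panel`) naming the offending cells.
#' @export
validate_panel <- function(p) {
  v <- p$values
  if (anyDuplicated(p$unit_ids))
    .err(sprintf("duplicate unit identifiers: %s",
                 paste(unique(p$unit_ids[duplicated(p$unit_ids)]), collapse = ", ")),
         "logtclub_duplicate_record")
  if (length(p$years) > 1) {
    d <- diff(p$years)
    if (any(d <= 0)) .err("years must be strictly increasing", "logtclub_invalid_panel")
    if (any(d != 1)) .err("years must be consecutive (annual panel)", "logtclub_invalid_panel")
  }
  if (anyNA(v)) {
    idx <- which(is.na(v), arr.ind = TRUE)
    cells <- paste(sprintf("(%s, %s)", p$unit_ids[idx[, 1]], p$years[idx[, 2]]),
                   collapse = ", ")
    .err(sprintf("unbalanced panel: missing cells %s", cells),
         "logtclub_unbalanced_panel")
  }
  if (!is.numeric(v)) .err("panel values must be numeric", "logtclub_invalid_panel")
  if (any(v <= 0)) {
    idx <- which(v <= 0, arr.ind = TRUE)[1, , drop = TRUE]
    .err(sprintf("non-positive density at (%s, %s): %g",
                 p$unit_ids[idx[1]], p$years[idx[2]], v[idx[1], idx[2]]),
         "logtclub_domain_error")
  }
  invisible(p)
}

.check_inference_dims <- function(p, min_units = 2, min_years = 10) {
  if (nrow(p$values) < min_units)
    .err(sprintf("at least %d units required, got %d", min_units, nrow(p$values)),
         "logtclub_insufficient_sample")
  if (ncol(p$values) < min_years)
    .err(sprintf("at least %d time points required, got %d", min_years, ncol(p$values)),
         "logtclub_insufficient_sample")
  invisible(p)
}

#' Read a density panel from CSV
#'
#' Loads a balanced panel from a long (one row per location-year) or wide (one
#' row per location, one column per year) CSV file, validating balance,
#' positivity and uniqueness. This is the ingestion path for extracts shaped
#' like the GBD Human Resources for Health tables (location, year, density per
#' 10,000 population).
#'
#' @param file Path or connection readable by [utils::read.csv()].
#' @param layout `"long"` or `"wide"`.
#' @param unit_col,year_col,value_col Column names for the long layout
#'   (defaults `location_name`, `year`, `value`). In the wide layout the first
#'   column is the location and remaining headers are years.
#' @return A validated [panel()].
#' @export
load_panel <- function(file, layout = c("long", "wide"),
                       unit_col = "location_name", year_col = "year",
                       value_col = "value") {
  layout <- match.arg(layout)
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "long") {
    missing_cols <- setdiff(c(unit_col, year_col, value_col), names(df))
    if (length(missing_cols))
      .err(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
           "logtclub_invalid_panel")
    units <- as.character(df[[unit_col]])
    yrs <- as.integer(df[[year_col]])
    vals <- as.numeric(df[[value_col]])
    key <- paste(units, yrs, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      .err(sprintf("duplicate record for (%s)", sub("\r", ", ", dup, fixed = TRUE)),
           "logtclub_duplicate_record")
    }
    uu <- sort(unique(units), method = "radix")
    yy <- sort(unique(yrs))
    m <- matrix(NA_real_, length(uu), length(yy), dimnames = list(uu, yy))
    m[cbind(match(units, uu), match(yrs, yy))] <- vals
    panel(m, uu, yy)
  } else {
    if (ncol(df) < 2)
      .err("wide layout needs a location column plus year columns",
           "logtclub_invalid_panel")
    units <- as.character(df[[1]])
    yy <- as.integer(names(df)[-1])
    if (anyNA(yy))
      .err("wide layout headers after the first column must be years",
           "logtclub_invalid_panel")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- list(units, yy)
    panel(m, units, yy)
  }
}

#' Write a density panel to CSV
#'
#' Emits the same long/wide CSV dialects [load_panel()] reads. Values are
#' written with full double precision so a load/write round trip is
#' value-exact to at least 15 significant digits.
#'
#' @inheritParams load_panel
#' @param p A `conv_panel`.
#' @return The file path, invisibly.
#' @export
write_panel <- function(p, file, layout = c("long", "wide"),
                        unit_col = "location_name", year_col = "year",
                        value_col = "value") {
  layout <- match.arg(layout)
  if (layout == "long") {
    df <- data.frame(
      u = rep(p$unit_ids, times = length(p$years)),
      y = rep(p$years, each = length(p$unit_ids)),
      v = as.vector(p$values),
      stringsAsFactors = FALSE
    )
    names(df) <- c(unit_col, year_col, value_col)
  } else {
    df <- data.frame(location = p$unit_ids, p$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @export
print.conv_panel <- function(x, ...) {
  cat(sprintf("Balanced density panel: %d units x %d years (%d-%d)\n",
              length(x$unit_ids), length(x$years), min(x$years), max(x$years)))
  cat(sprintf("  density range: %.3g - %.3g per 10,000\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Subset a panel by unit
#'
#' @param p A `conv_panel`.
#' @param units Character vector of unit ids to keep.
#' @return A `conv_panel` containing only `units` (re-sorted lexicographically).
#' @export
subset_panel <- function(p, units) {
  missing_units <- setdiff(units, p$unit_ids)
  if (length(missing_units))
    .err(sprintf("unknown units: %s", paste(missing_units, collapse = ", ")),
         "logtclub_invalid_panel")
  panel(p$values[units, , drop = FALSE], units, p$years)
}
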