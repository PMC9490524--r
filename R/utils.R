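#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a validation failure
#'
#' All input problems raise a condition of class `bs_validation_error` that
#' carries the complete list of violations found in one pass, plus flags
#' distinguishing an incomplete record (answers missing) from a malformed one
#' (unknown items, out-of-range codes, bad types).
#'
#' @param violations character vector describing each violation.
#' @param incomplete logical; at least one required answer is missing.
#' @param malformed logical; at least one answer or field is structurally bad.
#' @keywords internal
bs_abort_validation <- function(violations, incomplete = FALSE, malformed = FALSE) {
  stop(structure(
    class = c("bs_validation_error", "error", "condition"),
    list(
      message = paste0(
        "validation failed (",
        paste(c(if (incomplete) "incomplete", if (malformed) "malformed"), collapse = ", "),
        "):\n", paste0("  - ", violations, collapse = "\n")
      ),
      call = sys.call(-1),
      violations = violations,
      incomplete = incomplete,
      malformed = malformed
    )
  ))
}

#' Parse a timestamp into a UTC POSIXct instant
#'
#' Accepts POSIXct, Date, or an ISO-8601 string; everything is normalised to
#' UTC so that record ordering is unambiguous.
#' @param x timestamp-like input.
#' @return POSIXct of length 1 in UTC.
#' @keywords internal
bs_parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(format(x), tz = "UTC"))
  }
  if (is.character(x) && length(x) == 1L) {
    fmt <- if (grepl("T", x, fixed = TRUE)) "%Y-%m-%dT%H:%M:%S" else
      if (grepl(":", x, fixed = TRUE)) "%Y-%m-%d %H:%M:%S" else "%Y-%m-%d"
    out <- as.POSIXct(sub("Z$", "", x), format = fmt, tz = "UTC")
    if (!is.na(out)) return(out)
  }
  bs_abort_validation(
    sprintf("cannot parse timestamp: %s", paste(format(x), collapse = " ")),
    malformed = TRUE
  )
}

bs_format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Add calendar months with end-of-month clamping
#'
#' `2022-11-30` plus three months is `2023-02-28`: when the target month is
#' shorter than the source day-of-month, the result clamps to the last day of
#' the target month rather than rolling over.
#' @param date a `Date`.
#' @param months integer number of calendar months (may be 0).
#' @return a `Date`.
#' @keywords internal
bs_add_months <- function(date, months) {
  stopifnot(inherits(date, "Date"), length(date) == 1L)
  lt <- as.POSIXlt(date)
  total <- lt$mon + as.integer(months)
  year <- lt$year + 1900L + total %/% 12L
  month <- total %% 12L + 1L
  last_day <- as.integer(format(
    as.Date(sprintf("%d-%02d-01", year + (month == 12L), month %% 12L + 1L)) - 1L,
    "%d"
  ))
  day <- min(lt$mday, last_day)
  as.Date(sprintf("%d-%02d-%02d", year, month, day))
}
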