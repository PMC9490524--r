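#' Longitudinal test history
#'
#' A history collects one respondent's test records in chronological order so
#' their burnout evolution can be tracked between the recommended 3-monthly
#' retests.
#'
#' @param respondent_id opaque respondent key.
#' @param records optional list of `bs_test_record`s (any order; duplicated
#'   timestamps are rejected).
#' @return a `bs_history`.
#' @export
new_history <- function(respondent_id, records = list()) {
  h <- structure(list(respondent_id = as.character(respondent_id),
                      records = list()),
                 class = "bs_history")
  for (r in records) h <- append_record(h, r)
  h
}

#' @export
print.bs_history <- function(x, ...) {
  cat(sprintf("<history %s: %d records>\n", x$respondent_id,
              length(x$records)))
  invisible(x)
}

#' Append a test record to a history
#'
#' Inserts the record while keeping the history sorted by timestamp.
#' Records for a different respondent, and records duplicating an existing
#' timestamp, are rejected.
#'
#' @param history a `bs_history`.
#' @param record a `bs_test_record` for the same respondent.
#' @return the updated `bs_history`.
#' @export
append_record <- function(history, record) {
  stopifnot(inherits(history, "bs_history"), inherits(record, "bs_test_record"))
  if (!identical(record$respondent_id, history$respondent_id)) {
    bs_abort_validation(
      sprintf("record respondent '%s' does not match history '%s'",
              record$respondent_id, history$respondent_id),
      malformed = TRUE
    )
  }
  existing <- vapply(history$records,
                     function(r) as.numeric(r$timestamp), numeric(1))
  if (as.numeric(record$timestamp) %in% existing) {
    bs_abort_validation(
      sprintf("duplicate timestamp: %s", bs_format_timestamp(record$timestamp)),
      malformed = TRUE
    )
  }
  recs <- c(history$records, list(record))
  ts <- vapply(recs, function(r) as.numeric(r$timestamp), numeric(1))
  history$records <- recs[order(ts)]
  history
}

#' Chart series of the most recent diagnoses
#'
#' Returns the last `n` test records (default 4, as in the app's column
#' chart of the past four tests) in chronological order, as a tibble ready
#' for plotting: both the overall CBI risk and the combined diagnosis
#' category are carried so either can be charted.
#'
#' @param history a `bs_history`.
#' @param n maximum number of records, most recent first retained (>= 1).
#' @return a tibble with columns `timestamp`, `overall_risk`, `category`,
#'   oldest first; zero rows for an empty history.
#' @export
recent_diagnoses <- function(history, n = 4L) {
  stopifnot(inherits(history, "bs_history"), n >= 1)
  recs <- utils::tail(history$records, n)
  tibble::tibble(
    timestamp = as.POSIXct(
      vapply(recs, function(r) as.numeric(r$timestamp), numeric(1)),
      origin = "1970-01-01", tz = "UTC"
    ),
    overall_risk = vapply(recs, function(r) r$cbi$overall_risk, character(1)),
    category = vapply(recs, function(r) r$diagnosis$category, character(1))
  )
}

#' Per-dimension change since the previous test
#'
#' Compares the last two records' CBI subscale scores and labels each
#' dimension improved, unchanged or worsened. All CBI scales are
#' symptom-positive, so a *lower* score means improvement.
#'
#' @param history a `bs_history` with at least two records.
#' @return a tibble with columns `dimension`, `previous`, `current`, `trend`.
#' @export
dimension_deltas <- function(history) {
  stopifnot(inherits(history, "bs_history"))
  n <- length(history$records)
  if (n < 2L) {
    bs_abort_validation("insufficient history: need at least 2 records",
                        incomplete = TRUE)
  }
  prev <- history$records[[n - 1L]]
  cur <- history$records[[n]]
  dims <- c("personal", "work", "client")
  previous <- vapply(dims, function(d) prev$cbi[[d]]$score, numeric(1))
  current <- vapply(dims, function(d) cur$cbi[[d]]$score, numeric(1))
  tibble::tibble(
    dimension = dims,
    previous = unname(previous),
    current = unname(current),
    trend = ifelse(current < previous, "improved",
                   ifelse(current > previous, "worsened", "unchanged"))
  )
}

#' Wellness or alert message for a test record
#'
#' GHQ distress always produces an `"alert"` (the user is in a critical
#' state); if there is no distress and all three CBI subscales are exactly 0,
#' a `"congratulations"` message encourages the user to keep going; otherwise
#' `"none"`. Alert strictly dominates congratulations when both conditions
#' hold.
#'
#' @param record a `bs_test_record`.
#' @return `"alert"`, `"congratulations"` or `"none"`.
#' @export
status_message <- function(record) {
  stopifnot(inherits(record, "bs_test_record"))
  if (record$ghq$distress) return("alert")
  scores <- vapply(c("personal", "work", "client"),
                   function(d) record$cbi[[d]]$score, numeric(1))
  if (all(scores == 0)) "congratulations" else "none"
}

#' Next recommended retest date
#'
#' Self-administered screening should be repeated every 3 months; this
#' advances a record's timestamp by that interval in calendar months, with
#' end-of-month clamping (2022-11-30 plus 3 months is 2023-02-28).
#'
#' @param record a `bs_test_record`.
#' @param interval_months calendar months until the retest (default 3).
#' @return a `Date`.
#' @export
next_due <- function(record, interval_months = 3L) {
  stopifnot(inherits(record, "bs_test_record"))
  bs_add_months(as.Date(record$timestamp, tz = "UTC"),
                as.integer(interval_months))
}
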