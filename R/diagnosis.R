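#' Four-outcome burnout diagnosis
#'
#' Combines the GHQ-12 distress flag with the overall CBI burnout risk into
#' the screening app's four possible outcomes:
#'
#' * **critical** — distress on the GHQ and high burnout risk on the CBI;
#' * **moderate** — moderate burnout risk on the CBI, regardless of the GHQ;
#' * **great** — no distress on the GHQ and low burnout risk on the CBI;
#' * **contradictory** — the remaining two combinations (distress with low
#'   risk, or no distress with high risk); the two instruments disagree and a
#'   retest is recommended.
#'
#' The mapping is total over the six (distress, risk) combinations. The
#' outcome is a screening aid, not a medical diagnosis.
#'
#' @param ghq a `bs_ghq_result` from [score_ghq()].
#' @param cbi a `bs_cbi_result` from [score_cbi()].
#' @return a `bs_diagnosis`: list with `category` and a human-readable
#'   `rationale` naming the rule that fired.
#' @export
diagnose <- function(ghq, cbi) {
  stopifnot(inherits(ghq, "bs_ghq_result"), inherits(cbi, "bs_cbi_result"))
  risk <- cbi$overall_risk
  if (risk == "moderate") {
    new_diagnosis("moderate",
                  "moderate burnout risk on the CBI (independently of the GHQ)")
  } else if (ghq$distress && risk == "high") {
    new_diagnosis("critical",
                  "distress on the GHQ and high burnout risk on the CBI")
  } else if (!ghq$distress && risk == "low") {
    new_diagnosis("great",
                  "no distress on the GHQ and low burnout risk on the CBI")
  } else if (ghq$distress) {
    new_diagnosis("contradictory",
                  "GHQ distress but low CBI burnout risk; repeat the tests")
  } else {
    new_diagnosis("contradictory",
                  "high CBI burnout risk but no GHQ distress; repeat the tests")
  }
}

new_diagnosis <- function(category, rationale) {
  structure(list(category = category, rationale = rationale),
            class = "bs_diagnosis")
}

#' @export
print.bs_diagnosis <- function(x, ...) {
  cat(sprintf("<diagnosis: %s — %s>\n", x$category, x$rationale))
  invisible(x)
}

#' Score both instruments and bundle a timestamped test record
#'
#' Validates and scores a paired GHQ-12 and CBI administration for the same
#' respondent, derives the four-outcome diagnosis, and stamps the record so
#' it can be appended to a monitoring history.
#'
#' @param ghq_response GHQ-12 `bs_response_record`.
#' @param cbi_response CBI `bs_response_record` for the same respondent.
#' @param now record timestamp (defaults to the later of the two response
#'   timestamps).
#' @param threshold GHQ distress threshold, see [score_ghq()].
#' @return a `bs_test_record`: list with `respondent_id`, `timestamp`, `ghq`,
#'   `cbi` and `diagnosis`.
#' @export
make_record <- function(ghq_response, cbi_response, now = NULL, threshold = 3L) {
  stopifnot(inherits(ghq_response, "bs_response_record"),
            inherits(cbi_response, "bs_response_record"))
  if (!identical(ghq_response$respondent_id, cbi_response$respondent_id)) {
    bs_abort_validation(
      sprintf("respondent mismatch: '%s' vs '%s'",
              ghq_response$respondent_id, cbi_response$respondent_id),
      malformed = TRUE
    )
  }
  ghq <- score_ghq(ghq_response, threshold = threshold)
  cbi <- score_cbi(cbi_response)
  ts <- if (is.null(now)) {
    max(ghq_response$timestamp, cbi_response$timestamp)
  } else {
    bs_parse_timestamp(now)
  }
  structure(
    list(
      respondent_id = ghq_response$respondent_id,
      timestamp = ts,
      ghq = ghq,
      cbi = cbi,
      diagnosis = diagnose(ghq, cbi)
    ),
    class = "bs_test_record"
  )
}

#' @export
print.bs_test_record <- function(x, ...) {
  cat(sprintf("<test record %s @ %s>\n", x$respondent_id,
              bs_format_timestamp(x$timestamp)))
  print(x$ghq)
  print(x$cbi)
  print(x$diagnosis)
  invisible(x)
}
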