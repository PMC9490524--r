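#' Bimodal coding of a single GHQ-12 answer
#'
#' GHQ-12 items are scored bimodally: the two most positive options (codes 0
#' and 1) contribute 0 points, the two most negative (codes 2 and 3)
#' contribute 1 point. The pattern is uniform across all twelve items.
#'
#' @param item a GHQ-12 item from the built-in bank.
#' @param code option code 0..3 or an answer label for that item.
#' @return 0 or 1.
#' @export
code_ghq_answer <- function(item, code) {
  if (!identical(item$instrument, "GHQ12")) {
    bs_abort_validation(sprintf("item %s is not a GHQ12 item",
                                item$id %||% "<unknown>"), malformed = TRUE)
  }
  resolved <- bs_resolve_answer(item, code)
  if (is.na(resolved)) {
    bs_abort_validation(sprintf("invalid answer for item %s: %s", item$id,
                                paste(format(code), collapse = " ")),
                        malformed = TRUE)
  }
  as.integer(resolved >= 2L)
}

#' Score a GHQ-12 response
#'
#' The total score is the sum of the bimodally coded answers, range 0–12.
#' The distress flag compares the total against a configurable threshold; the
#' screening default is 3 — deliberately below the conventional cut-off so
#' that no symptoms are ignored. The conventional interpretation is always
#' reported alongside in `standard_band`: a total of 4 or more suggests
#' possible mental distress, 8 or more the presence of various stress-related
#' psychological disorders.
#'
#' @param response a validated (or validatable) GHQ-12 `bs_response_record`.
#' @param threshold integer 0..12; score >= threshold sets the distress flag.
#' @return a `bs_ghq_result`: list with `score`, `threshold`, `distress`, and
#'   `standard_band` (`"none"`, `"possible_distress"` or `"stress_disorders"`).
#' @examples
#' ghq <- load_builtin_instruments()$GHQ12
#' worst <- response_record("GHQ12", "r1",
#'   setNames(rep(3, 12), names(ghq$items)), "2022-01-15")
#' score_ghq(worst)$score  # 12
#' @export
score_ghq <- function(response, threshold = 3L) {
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 12)
  ghq <- load_builtin_instruments()$GHQ12
  response <- validate_response(ghq, response)
  score <- sum(vapply(
    names(response$answers),
    function(id) code_ghq_answer(ghq$items[[id]], response$answers[[id]]),
    integer(1)
  ))
  new_ghq_result(score, as.integer(threshold))
}

new_ghq_result <- function(score, threshold) {
  structure(
    list(
      score = as.integer(score),
      threshold = as.integer(threshold),
      distress = score >= threshold,
      standard_band = if (score >= 8L) "stress_disorders"
        else if (score >= 4L) "possible_distress" else "none"
    ),
    class = "bs_ghq_result"
  )
}

#' @export
print.bs_ghq_result <- function(x, ...) {
  cat(sprintf("<GHQ-12: score %d/12, distress %s (threshold %d), band %s>\n",
              x$score, if (x$distress) "YES" else "no", x$threshold,
              x$standard_band))
  invisible(x)
}
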