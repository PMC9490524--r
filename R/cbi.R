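#' Point value of a single CBI answer
#'
#' CBI options are valued 100, 75, 50, 25, 0 from highest to lowest intensity
#' (codes 0..4 in printed order). For the single reverse-scored item — the
#' positively worded work-dimension energy question — the mapping is
#' inverted: 0, 25, 50, 75, 100, so that a high value always means more
#' burnout.
#'
#' @param item a CBI item from the built-in bank.
#' @param code option code 0..4 or an answer label (either answer pack).
#' @return points in \{0, 25, 50, 75, 100\}.
#' @export
code_cbi_answer <- function(item, code) {
  if (!identical(item$instrument, "CBI")) {
    bs_abort_validation(sprintf("item %s is not a CBI item",
                                item$id %||% "<unknown>"), malformed = TRUE)
  }
  resolved <- bs_resolve_answer(item, code)
  if (is.na(resolved)) {
    bs_abort_validation(sprintf("invalid answer for item %s: %s", item$id,
                                paste(format(code), collapse = " ")),
                        malformed = TRUE)
  }
  if (isTRUE(item$reverse)) 25 * resolved else 25 * (4L - resolved)
}

#' Classify a CBI subscale score into a burnout level
#'
#' Subscale cut-offs: below 50 is low, 50 up to (but excluding) 75 is
#' moderate, 75 and above is high. For a 6-item subscale no attainable mean
#' falls strictly between 74 and 75, so the half-open moderate band loses
#' nothing.
#'
#' @param score points in \[0, 100\].
#' @return `"low"`, `"moderate"` or `"high"`.
#' @export
classify_level <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score < 0 || score > 100) {
    bs_abort_validation(sprintf("score outside [0, 100]: %s",
                                paste(format(score), collapse = " ")),
                        malformed = TRUE)
  }
  if (score < 50) "low" else if (score < 75) "moderate" else "high"
}

#' Score one CBI dimension
#'
#' The dimension score is the arithmetic mean of the point values of its
#' items (reverse item already inverted), on the 0–100 scale, with its
#' low/moderate/high level attached.
#'
#' @param response a validated (or validatable) CBI `bs_response_record`.
#' @param dimension `"personal"`, `"work"` or `"client"`.
#' @return a `bs_dimension_score`: list with `dimension`, `score`, `level`.
#' @export
score_dimension <- function(response, dimension = c("personal", "work", "client")) {
  dimension <- match.arg(dimension)
  cbi <- load_builtin_instruments()$CBI
  response <- validate_response(cbi, response)
  bs_score_dimension_validated(cbi, response, dimension)
}

bs_score_dimension_validated <- function(cbi, response, dimension) {
  ids <- names(cbi$items)[
    vapply(cbi$items, `[[`, "", "dimension") == dimension
  ]
  pts <- vapply(ids, function(id)
    code_cbi_answer(cbi$items[[id]], response$answers[[id]]), numeric(1))
  score <- mean(pts)
  structure(
    list(dimension = dimension, score = score, level = classify_level(score)),
    class = "bs_dimension_score"
  )
}

#' Combine three subscale levels into an overall CBI risk
#'
#' The overall burnout risk is read off the three subscale levels:
#' * **high** — two or three high subscales;
#' * **moderate** — exactly one high subscale, or at least two moderate ones;
#' * **low** — otherwise (all low, or a single moderate).
#'
#' The rule is total over all 27 level combinations and monotone: raising any
#' one subscale's level never lowers the overall risk. A single high subscale
#' is deliberately kept at moderate rather than low — one severely affected
#' dimension should never produce an all-clear.
#'
#' @param levels character vector of exactly three values in
#'   `c("low", "moderate", "high")` (personal, work, client — order
#'   irrelevant).
#' @return `"low"`, `"moderate"` or `"high"`.
#' @examples
#' combine_risk(c("low", "low", "moderate"))   # "low"
#' combine_risk(c("high", "high", "low"))      # "high"
#' @export
combine_risk <- function(levels) {
  if (length(levels) != 3L || !all(levels %in% c("low", "moderate", "high"))) {
    bs_abort_validation("levels must be three of low/moderate/high",
                        malformed = TRUE)
  }
  n_high <- sum(levels == "high")
  n_mod <- sum(levels == "moderate")
  if (n_high >= 2L) "high"
  else if (n_high == 1L || n_mod >= 2L) "moderate"
  else "low"
}

#' Score a full CBI response
#'
#' Scores the three subscales (personal, work-related, client-related) and
#' combines their levels into the overall burnout risk.
#'
#' @param response a validated (or validatable) CBI `bs_response_record`.
#' @return a `bs_cbi_result`: list with `personal`, `work`, `client` (each a
#'   `bs_dimension_score`) and `overall_risk`.
#' @examples
#' cbi <- load_builtin_instruments()$CBI
#' rec <- response_record("CBI", "r1",
#'   setNames(rep("Always", 19), names(cbi$items)), "2022-01-15")
#' score_cbi(rec)$overall_risk  # "high"
#' @export
score_cbi <- function(response) {
  cbi <- load_builtin_instruments()$CBI
  response <- validate_response(cbi, response)
  dims <- lapply(c(personal = "personal", work = "work", client = "client"),
                 function(d) bs_score_dimension_validated(cbi, response, d))
  structure(
    c(dims, list(overall_risk = combine_risk(
      vapply(dims, `[[`, "", "level")
    ))),
    class = "bs_cbi_result"
  )
}

#' @export
print.bs_cbi_result <- function(x, ...) {
  for (d in c("personal", "work", "client")) {
    cat(sprintf("  %-8s %6.2f  %s\n", d, x[[d]]$score, x[[d]]$level))
  }
  cat(sprintf("<CBI overall risk: %s>\n", x$overall_risk))
  invisible(x)
}
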