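#' Score one System Usability Scale response
#'
#' The SUS is a 10-item usability questionnaire answered 1 (strongly
#' disagree) to 5 (strongly agree). Odd-numbered items are positively worded
#' and contribute `(x - 1) * 2.5` points; even-numbered items are negatively
#' worded and contribute `(5 - x) * 2.5`. Each item is thus worth 0–10 points
#' and the total ranges 0–100.
#'
#' @param answers integer vector of exactly 10 values in 1..5, positionally
#'   items 1..10.
#' @return score in \[0, 100\].
#' @examples
#' score_sus(rep(c(5, 1), 5))  # 100
#' score_sus(rep(3, 10))       # 50
#' @export
score_sus <- function(answers) {
  answers <- bs_check_sus_answers(answers)
  odd <- answers[seq(1, 9, by = 2)]
  even <- answers[seq(2, 10, by = 2)]
  sum((odd - 1) * 2.5) + sum((5 - even) * 2.5)
}

bs_check_sus_answers <- function(answers) {
  if (!is.numeric(answers) || length(answers) != 10L || anyNA(answers) ||
      any(answers != round(answers)) || any(answers < 1 | answers > 5)) {
    bs_abort_validation("a SUS response is 10 integer answers in 1..5",
                        malformed = TRUE)
  }
  as.integer(answers)
}

#' Build a SUS count table
#'
#' Aggregated survey results are often published as a count table: for each
#' of the 10 items, how many of the n respondents chose each of the five
#' options. The bundled `sus_survey_counts.csv` fixture holds the 40-user
#' field evaluation of the screening app in this format.
#'
#' @param counts 10 x 5 numeric matrix (or data frame); rows are items 1..10,
#'   columns are answer options 1..5.
#' @param n expected respondent count; every row must sum to `n` (defaults to
#'   the first row's sum).
#' @return a `bs_sus_counts`: list with `counts` (integer matrix) and `n`.
#' @export
sus_count_table <- function(counts, n = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || !identical(dim(counts), c(10L, 5L)) ||
      anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bs_abort_validation("counts must be a 10x5 nonnegative integer matrix",
                        malformed = TRUE)
  }
  sums <- rowSums(counts)
  n <- as.integer(n %||% sums[[1]])
  if (any(sums != n)) {
    bs_abort_validation(
      sprintf("item %d counts sum to %d, expected n = %d",
              which(sums != n), sums[sums != n], n),
      malformed = TRUE
    )
  }
  dimnames(counts) <- list(item = 1:10, answer = 1:5)
  structure(list(counts = matrix(as.integer(counts), 10, 5,
                                 dimnames = dimnames(counts)),
                 n = n),
            class = "bs_sus_counts")
}

#' Mean SUS score from an aggregated count table
#'
#' The SUS total is linear in the per-item contributions, so the cohort mean
#' can be computed exactly from counts without reconstructing individual
#' respondents: each item's mean contribution is the count-weighted average
#' of its option values, and the cohort mean is their sum. For any
#' disaggregation consistent with the counts this equals the mean of the
#' per-respondent scores.
#'
#' @param table a `bs_sus_counts` from [sus_count_table()].
#' @return mean score in \[0, 100\].
#' @examples
#' tab <- read_sus_counts(system.file("extdata", "sus_survey_counts.csv",
#'                                    package = "burnoutscreen"))
#' mean_sus_from_counts(tab)  # 95.625
#' @export
mean_sus_from_counts <- function(table) {
  stopifnot(inherits(table, "bs_sus_counts"))
  x <- 1:5
  item_values <- rbind(
    odd = (x - 1) * 2.5,
    even = (5 - x) * 2.5
  )
  per_item <- vapply(1:10, function(i) {
    vals <- item_values[if (i %% 2 == 1) "odd" else "even", ]
    sum(table$counts[i, ] * vals) / table$n
  }, numeric(1))
  sum(per_item)
}

#' Interpret a SUS score
#'
#' Standard adjective bands: above 80.3 is excellent, 68 exactly is okay,
#' between 68 and 80.3 is good, 51 up to 68 is poor, below 51 is awful.
#' The published band edges overlap at 68; this partition keeps the printed
#' singleton ("68 = okay") and assigns (68, 80.3] to good and \[51, 68) to
#' poor, so every score in \[0, 100\] belongs to exactly one band.
#'
#' @param score numeric in \[0, 100\].
#' @return `"excellent"`, `"good"`, `"okay"`, `"poor"` or `"awful"`.
#' @export
interpret_sus <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score < 0 || score > 100) {
    bs_abort_validation(sprintf("SUS score outside [0, 100]: %s",
                                paste(format(score), collapse = " ")),
                        malformed = TRUE)
  }
  if (score > 80.3) "excellent"
  else if (score > 68) "good"
  else if (score == 68) "okay"
  else if (score >= 51) "poor"
  else "awful"
}

#' Full SUS report
#'
#' Convenience wrapper returning the score together with its interpretation
#' band, from either a single response or a count table.
#'
#' @param x a length-10 answer vector or a `bs_sus_counts`.
#' @return a `bs_sus_report`: list with `score`, `band` and `n`.
#' @export
sus_report <- function(x) {
  if (inherits(x, "bs_sus_counts")) {
    score <- mean_sus_from_counts(x)
    n <- x$n
  } else {
    score <- score_sus(x)
    n <- 1L
  }
  structure(list(score = score, band = interpret_sus(score), n = n),
            class = "bs_sus_report")
}

#' @export
print.bs_sus_report <- function(x, ...) {
  cat(sprintf("<SUS: %.4g (%s), n = %d>\n", x$score, x$band, x$n))
  invisible(x)
}

#' Read a SUS count table from CSV
#'
#' Expects columns `item` (1..10) and `resp_1`..`resp_5` (counts of answers
#' 1..5); any other columns (e.g. the question text) are ignored.
#'
#' @param path CSV file path.
#' @return a `bs_sus_counts`.
#' @export
read_sus_counts <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  needed <- c("item", paste0("resp_", 1:5))
  if (!all(needed %in% names(df))) {
    bs_abort_validation(sprintf("missing column: %s",
                                setdiff(needed, names(df))),
                        malformed = TRUE)
  }
  df <- df[order(df$item), ]
  if (!identical(as.integer(df$item), 1:10)) {
    bs_abort_validation("items must be exactly 1..10", malformed = TRUE)
  }
  sus_count_table(as.matrix(df[paste0("resp_", 1:5)]))
}

#' Aggregate per-respondent SUS responses into a count table
#'
#' @param responses list (or 10-column matrix, respondents in rows) of
#'   length-10 answer vectors.
#' @return a `bs_sus_counts`.
#' @export
aggregate_sus <- function(responses) {
  if (is.matrix(responses)) {
    responses <- lapply(seq_len(nrow(responses)), function(i) responses[i, ])
  }
  responses <- lapply(responses, bs_check_sus_answers)
  counts <- matrix(0L, 10, 5)
  for (r in responses) {
    for (i in 1:10) counts[i, r[[i]]] <- counts[i, r[[i]]] + 1L
  }
  sus_count_table(counts, n = length(responses))
}
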