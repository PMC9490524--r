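#' Synthetic respondent profile
#'
#' A profile parameterises the seeded simulator: how distressed and how
#' burned out a synthetic respondent is, and how they rate usability. The
#' defaults describe a mildly loaded but non-clinical respondent — occasional
#' negative GHQ answers, low-range burnout with realistic item-to-item
#' variability, and the strongly positive usability ratings observed in the
#' app's field evaluation.
#'
#' @param ghq_negativity probability in \[0, 1\] that a GHQ item is answered
#'   in its 1-coded (symptomatic) half.
#' @param cbi_target named numeric vector `c(personal=, work=, client=)` of
#'   target subscale means on the 0–100 scale.
#' @param cbi_noise spread parameter >= 0: per-item probability of a one-step
#'   option displacement (values above 1 are clamped to 1).
#' @param sus_positivity probability in \[0, 1\] that a SUS item is answered
#'   optimally.
#' @return a `bs_profile`.
#' @export
respondent_profile <- function(ghq_negativity = 0.2,
                               cbi_target = c(personal = 30, work = 30, client = 30),
                               cbi_noise = 0.5,
                               sus_positivity = 0.9) {
  if (length(cbi_target) == 1L && is.null(names(cbi_target))) {
    cbi_target <- c(personal = cbi_target, work = cbi_target,
                    client = cbi_target)
  }
  stopifnot(
    ghq_negativity >= 0, ghq_negativity <= 1,
    all(c("personal", "work", "client") %in% names(cbi_target)),
    all(cbi_target >= 0 & cbi_target <= 100),
    cbi_noise >= 0,
    sus_positivity >= 0, sus_positivity <= 1
  )
  structure(
    list(ghq_negativity = ghq_negativity,
         cbi_target = cbi_target[c("personal", "work", "client")],
         cbi_noise = cbi_noise,
         sus_positivity = sus_positivity),
    class = "bs_profile"
  )
}

#' Simulate a GHQ-12 response
#'
#' Each item is independently answered from its 1-coded (symptomatic) option
#' pair with probability `ghq_negativity`, otherwise from the 0-coded pair;
#' within a pair the option is chosen uniformly. The bimodal total is
#' therefore Binomial(12, `ghq_negativity`).
#'
#' @param profile a `bs_profile`.
#' @param seed integer seed; the same seed reproduces the same record.
#' @param respondent_id,timestamp passed through to the record.
#' @return a validated GHQ-12 `bs_response_record`.
#' @export
simulate_ghq <- function(profile, seed, respondent_id = "sim",
                         timestamp = "2022-01-01T00:00:00Z") {
  stopifnot(inherits(profile, "bs_profile"))
  ghq <- load_builtin_instruments()$GHQ12
  codes <- withr::with_seed(as.integer(seed), {
    neg <- stats::runif(12) < profile$ghq_negativity
    within_pair <- sample(0:1, 12, replace = TRUE)
    ifelse(neg, 2L, 0L) + within_pair
  })
  rec <- response_record("GHQ12", respondent_id,
                         stats::setNames(as.list(codes), names(ghq$items)),
                         timestamp)
  validate_response(ghq, rec)
}

#' Simulate a CBI response
#'
#' Noise-free base: within each dimension the items are split between the two
#' answer options flanking the target mean ("bracketing"), so the noise-free
#' subscale mean is the attainable mean closest to the target — with noise 0
#' the classified level therefore recovers `classify_level(target)` for any
#' target further than `25/(2n)` points from a level cut-off. On top of the
#' base, each item's option is independently displaced one step up or down
#' with probability `cbi_noise / 2` each (clamped at the scale ends). The
#' reverse-scored work item is handled in coded (burnout-point) space, so the
#' target applies to its contribution, not its raw option.
#'
#' @inheritParams simulate_ghq
#' @return a validated CBI `bs_response_record`.
#' @export
simulate_cbi <- function(profile, seed, respondent_id = "sim",
                         timestamp = "2022-01-01T00:00:00Z") {
  stopifnot(inherits(profile, "bs_profile"))
  cbi <- load_builtin_instruments()$CBI
  dims <- vapply(cbi$items, `[[`, "", "dimension")
  p_step <- min(profile$cbi_noise, 1) / 2
  codes <- withr::with_seed(as.integer(seed), {
    out <- stats::setNames(integer(length(cbi$items)), names(cbi$items))
    for (d in c("personal", "work", "client")) {
      ids <- names(dims)[dims == d]
      n <- length(ids)
      t <- profile$cbi_target[[d]]
      lo <- 25 * (t %/% 25)
      if (lo == t || lo == 100) {
        pts <- rep(t, n)
      } else {
        k <- round(n * (t - lo) / 25)
        pts <- rep(lo, n)
        pts[sample.int(n, k)] <- lo + 25
      }
      for (i in seq_along(ids)) {
        item <- cbi$items[[ids[[i]]]]
        code <- if (item$reverse) pts[[i]] / 25 else (100 - pts[[i]]) / 25
        u <- stats::runif(1)
        step <- if (u < p_step) -1L else if (u < 2 * p_step) 1L else 0L
        out[[ids[[i]]]] <- max(0L, min(4L, as.integer(code) + step))
      }
    }
    out
  })
  rec <- response_record("CBI", respondent_id, as.list(codes), timestamp)
  validate_response(cbi, rec)
}

#' Simulate a SUS response
#'
#' Each item is answered optimally (5 for positively worded odd items, 1 for
#' negatively worded even items) with probability `sus_positivity`, otherwise
#' uniformly over 1..5.
#'
#' @inheritParams simulate_ghq
#' @return integer vector of 10 answers in 1..5.
#' @export
simulate_sus <- function(profile, seed) {
  stopifnot(inherits(profile, "bs_profile"))
  withr::with_seed(as.integer(seed), {
    optimal <- rep(c(5L, 1L), 5)
    random <- sample(1:5, 10, replace = TRUE)
    ifelse(stats::runif(10) < profile$sus_positivity, optimal, random)
  })
}

#' Simulate a longitudinal test history
#'
#' Generates one combined GHQ+CBI test record per profile at successive
#' retest due dates (calendar-month steps from `start`), scored and diagnosed
#' with the package's own engines, and assembles them into a history. An
#' improving (or worsening) trajectory is simulated by passing a sequence of
#' profiles with decreasing (or increasing) severity.
#'
#' @param profiles list of `bs_profile`s, one per time point, in time order.
#' @param start `Date` (or parseable string) of the first test.
#' @param interval_months calendar months between tests (default 3).
#' @param seed integer seed governing all draws.
#' @param respondent_id respondent key for all records.
#' @param threshold GHQ distress threshold, see [score_ghq()].
#' @return a `bs_history` with `length(profiles)` records.
#' @export
simulate_history <- function(profiles, start = as.Date("2022-01-01"),
                             interval_months = 3L, seed = 1L,
                             respondent_id = "sim", threshold = 3L) {
  if (inherits(profiles, "bs_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "bs_profile")))
  start <- if (inherits(start, "Date")) start else as.Date(start)
  n <- length(profiles)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, 2L * n))
  history <- new_history(respondent_id)
  for (i in seq_len(n)) {
    ts <- as.POSIXct(paste(bs_add_months(start, (i - 1L) * interval_months),
                           "12:00:00"), tz = "UTC")
    ghq_rec <- simulate_ghq(profiles[[i]], sub_seeds[[2L * i - 1L]],
                            respondent_id, ts)
    cbi_rec <- simulate_cbi(profiles[[i]], sub_seeds[[2L * i]],
                            respondent_id, ts)
    history <- append_record(
      history, make_record(ghq_rec, cbi_rec, now = ts, threshold = threshold)
    )
  }
  history
}
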