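#' Built-in screening instruments
#'
#' The package ships the two questionnaires the screening engine is built on:
#'
#' * **GHQ-12** — the 12-item General Health Questionnaire, a screen for
#'   psychological distress over the past 30 days. Each item offers four
#'   response options ordered from most positive to most negative; under
#'   bimodal scoring the first two code 0 and the last two code 1.
#' * **CBI** — the 19-item Copenhagen Burnout Inventory with three subscales:
#'   personal (6 items), work-related (7 items) and client-related (6 items)
#'   burnout. Each item offers five options ordered from highest to lowest
#'   intensity, valued 100/75/50/25/0. One work item ("Do you have enough
#'   energy for family and friends during leisure time?") is positively worded
#'   and reverse-scored.
#'
#' Item ids are stable keys (`ghq.q01`..`ghq.q12`, `cbi.per.q1`..`cbi.per.q6`,
#' `cbi.wrk.q1`..`cbi.wrk.q7`, `cbi.cli.q1`..`cbi.cli.q6`) so stored responses
#' stay valid if wording or translation changes. CBI answers may use either of
#' two synonymous label packs (frequency wording "Always".."Never or almost
#' never", or degree wording "To a very high degree".."To a very low degree");
#' both map onto the same ordinal codes 0..4.
#'
#' @return `load_builtin_instruments()` returns a named list with components
#'   `GHQ12` and `CBI`, each a `bs_instrument`: a list with `id`, `version`,
#'   and `items` (a named list of items; each item has `id`, `text`,
#'   `instrument`, `dimension` (`"none"`, `"personal"`, `"work"` or
#'   `"client"`), `reverse`, `options` (character vector of labels in printed
#'   order, ordinal codes are positions minus one), `alt_options` (synonymous
#'   label pack or `NULL`) and `answer_pack`).
#' @examples
#' banks <- load_builtin_instruments()
#' length(banks$GHQ12$items)  # 12
#' length(banks$CBI$items)    # 19
#' @export
load_builtin_instruments <- function() {
  list(GHQ12 = bs_build_ghq12(), CBI = bs_build_cbi())
}

# GHQ-12 answer label sets. Four packs grouped by stem; the comparative pack
# varies its adjective per item (useful/capable/plain), so labels are stored
# per item and the pack key only records the family.
bs_ghq_packs <- list(
  ghq_variant_1 = c("Better than usual", "As usual",
                    "Less than usual", "Much less than usual"),
  ghq_variant_2 = c("Not at all", "No more than usual",
                    "A little more than usual", "Much more than usual"),
  ghq_variant_3 = c("More than usual", "As usual",
                    "Less than usual", "Much less than usual"),
  ghq_variant_4 = c("More capable than usual", "As usual",
                    "Less capable than usual", "Much less capable than usual")
)

bs_build_ghq12 <- function() {
  q <- list(
    list("Have you been able to concentrate well on what you did?",
         "ghq_variant_1", bs_ghq_packs$ghq_variant_1),
    list("Have your worries made you lose a lot of sleep?",
         "ghq_variant_2", bs_ghq_packs$ghq_variant_2),
    list("Have you felt that you play a useless role in life?",
         "ghq_variant_3", c("More useful than usual", "As usual",
                            "Less than usual", "Much less than usual")),
    list("Have you felt capable of making decisions?",
         "ghq_variant_3", bs_ghq_packs$ghq_variant_3),
    list("Have you felt under strain?",
         "ghq_variant_2", bs_ghq_packs$ghq_variant_2),
    list("Have you ever felt that you cannot overcome your difficulties?",
         "ghq_variant_2", bs_ghq_packs$ghq_variant_2),
    list("Have you been able to enjoy your activities every day?",
         "ghq_variant_3", bs_ghq_packs$ghq_variant_3),
    list("Have you been able to deal adequately with your problems?",
         "ghq_variant_4", bs_ghq_packs$ghq_variant_4),
    list("Have you felt unhappy and depressed?",
         "ghq_variant_2", bs_ghq_packs$ghq_variant_2),
    list("Have you lost confidence in yourself?",
         "ghq_variant_2", bs_ghq_packs$ghq_variant_2),
    list("Have you thought that you are useless?",
         "ghq_variant_2", bs_ghq_packs$ghq_variant_2),
    list("Do you feel reasonably happy, considering the circumstances?",
         "ghq_variant_3", c("More than usual", "Approximately the same as usual",
                            "Less than usual", "Much less than usual"))
  )
  items <- lapply(seq_along(q), function(i) {
    list(
      id = sprintf("ghq.q%02d", i),
      text = q[[i]][[1]],
      instrument = "GHQ12",
      dimension = "none",
      reverse = FALSE,
      options = q[[i]][[3]],
      alt_options = NULL,
      answer_pack = q[[i]][[2]]
    )
  })
  names(items) <- vapply(items, `[[`, "", "id")
  structure(list(id = "GHQ12", version = "1", items = items),
            class = "bs_instrument")
}

bs_cbi_packs <- list(
  cbi_pack_1 = c("Always", "Often", "Sometimes", "Seldom",
                 "Never or almost never"),
  cbi_pack_2 = c("To a very high degree", "To a high degree", "Somewhat",
                 "To a low degree", "To a very low degree")
)

bs_build_cbi <- function() {
  spec <- list(
    personal = c(
      "How often do you feel tired?",
      "How often are you physically exhausted?",
      "How often are you emotionally exhausted?",
      "How often do you think: “I can’t take it anymore”?",
      "How often do you feel worn out?",
      "How often do you feel weak and susceptible to illness?"
    ),
    work = c(
      "Is your work emotionally exhausting?",
      "Do you feel burned out because of your work?",
      "Does your work frustrate you?",
      "Do you feel worn out at the end of the working day?",
      "Are you exhausted in the morning at the thought of another day at work?",
      "Do you feel that every working hour is tiring for you?",
      "Do you have enough energy for family and friends during leisure time?"
    ),
    client = c(
      "Do you find it hard to work with clients?",
      "Do you find it frustrating to work with clients?",
      "Does it drain your energy to work with clients?",
      "Do you give more than you get back when you work with clients?",
      "Are you tired of working with clients?",
      "Do you wonder how long you will continue working with clients?"
    )
  )
  prefix <- c(personal = "cbi.per", work = "cbi.wrk", client = "cbi.cli")
  items <- list()
  for (dim in names(spec)) {
    texts <- spec[[dim]]
    # frequency wording takes pack 1, degree wording pack 2; both label packs
    # are accepted for any item at validation/coding time
    pack <- if (dim == "personal") "cbi_pack_1" else "cbi_pack_2"
    for (i in seq_along(texts)) {
      id <- sprintf("%s.q%d", prefix[[dim]], i)
      items[[id]] <- list(
        id = id,
        text = texts[[i]],
        instrument = "CBI",
        dimension = dim,
        reverse = dim == "work" && i == 7L,
        options = bs_cbi_packs[[pack]],
        alt_options = bs_cbi_packs[[setdiff(names(bs_cbi_packs), pack)]],
        answer_pack = pack
      )
    }
  }
  structure(list(id = "CBI", version = "1", items = items),
            class = "bs_instrument")
}

#' @export
print.bs_instrument <- function(x, ...) {
  cat(sprintf("<instrument %s: %d items>\n", x$id, length(x$items)))
  dims <- table(vapply(x$items, `[[`, "", "dimension"))
  if (!identical(names(dims), "none")) {
    cat("  dimensions:",
        paste(sprintf("%s=%d", names(dims), as.integer(dims)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Create a response record
#'
#' A response record holds one respondent's answers to one instrument at one
#' point in time. Answers are keyed by item id and stored as ordinal option
#' codes (0-based positions in the item's printed option list); labels from
#' either CBI answer pack, or the item's own GHQ labels, are resolved to codes.
#'
#' @param instrument_id `"GHQ12"` or `"CBI"`.
#' @param respondent_id opaque respondent key.
#' @param answers named vector or list mapping item id to option code or
#'   answer label.
#' @param timestamp time of administration (ISO-8601 string, `Date`, or
#'   `POSIXct`); stored as a UTC instant. Defaults to the current time.
#' @return a `bs_response_record`.
#' @seealso [validate_response()]
#' @export
response_record <- function(instrument_id, respondent_id, answers,
                            timestamp = Sys.time()) {
  stopifnot(is.character(instrument_id), length(instrument_id) == 1L)
  answers <- as.list(answers)
  structure(
    list(
      instrument_id = instrument_id,
      respondent_id = as.character(respondent_id),
      timestamp = bs_parse_timestamp(timestamp),
      answers = answers
    ),
    class = "bs_response_record"
  )
}

#' @export
print.bs_response_record <- function(x, ...) {
  cat(sprintf("<response %s / %s @ %s: %d answers>\n", x$instrument_id,
              x$respondent_id, bs_format_timestamp(x$timestamp),
              length(x$answers)))
  invisible(x)
}

# Resolve one raw answer (code or label) for an item to an integer code,
# or NA with an explanation attribute.
bs_resolve_answer <- function(item, value) {
  n_opt <- length(item$options)
  if (is.numeric(value) && length(value) == 1L && !is.na(value) &&
      value == round(value)) {
    code <- as.integer(value)
    if (code >= 0L && code < n_opt) return(code)
    return(NA_integer_)
  }
  if (is.character(value) && length(value) == 1L) {
    hit <- match(value, item$options)
    if (is.na(hit) && !is.null(item$alt_options)) {
      hit <- match(value, item$alt_options)
    }
    if (!is.na(hit)) return(hit - 1L)
  }
  NA_integer_
}

#' Validate a response record against an instrument
#'
#' Checks that a record is addressed to the given instrument, answers every
#' item, refers only to known items, and uses only valid option codes or
#' labels. All violations are collected in a single pass and reported
#' together; the error condition distinguishes *incomplete* (missing answers)
#' from *malformed* (unknown items or invalid codes). Incomplete records are
#' rejected outright — both instruments are short and no prorating rule is
#' defined for them.
#'
#' @param instrument a `bs_instrument` from [load_builtin_instruments()].
#' @param record a `bs_response_record`.
#' @return the record, with all answers normalised to integer codes, invisibly
#'   classified valid.
#' @examples
#' cbi <- load_builtin_instruments()$CBI
#' ans <- setNames(rep("Always", 19), names(cbi$items))
#' rec <- response_record("CBI", "r1", ans, "2022-01-15")
#' rec <- validate_response(cbi, rec)
#' @export
validate_response <- function(instrument, record) {
  stopifnot(inherits(instrument, "bs_instrument"),
            inherits(record, "bs_response_record"))
  violations <- character()
  incomplete <- FALSE
  malformed <- FALSE
  if (!identical(record$instrument_id, instrument$id)) {
    bs_abort_validation(
      sprintf("record is for instrument '%s', not '%s'",
              record$instrument_id, instrument$id),
      malformed = TRUE
    )
  }
  item_ids <- names(instrument$items)
  ans_ids <- names(record$answers)
  if (is.null(ans_ids) && length(record$answers) > 0L) {
    bs_abort_validation("answers must be named by item id", malformed = TRUE)
  }
  unknown <- setdiff(ans_ids, item_ids)
  if (length(unknown)) {
    malformed <- TRUE
    violations <- c(violations, sprintf("unknown item id: %s", unknown))
  }
  missing <- setdiff(item_ids, ans_ids)
  if (length(missing)) {
    incomplete <- TRUE
    violations <- c(violations, sprintf("missing answer for item: %s", missing))
  }
  coded <- list()
  for (id in intersect(ans_ids, item_ids)) {
    code <- bs_resolve_answer(instrument$items[[id]], record$answers[[id]])
    if (is.na(code)) {
      malformed <- TRUE
      violations <- c(violations, sprintf(
        "invalid answer for item %s: %s", id,
        paste(format(record$answers[[id]]), collapse = " ")
      ))
    } else {
      coded[[id]] <- code
    }
  }
  if (length(violations)) {
    bs_abort_validation(violations, incomplete = incomplete,
                        malformed = malformed)
  }
  record$answers <- coded[item_ids]
  record
}

#' Seeded presentation order for an instrument
#'
#' Questionnaire items should not be presented in their printed, dimension-
#' blocked order: mixing items across topics is recommended to avoid
#' stereotypical response patterns. This returns a deterministic, seeded
#' permutation of the instrument's item ids; for the CBI the permutation
#' additionally avoids runs of more than three same-dimension items.
#'
#' @param instrument a `bs_instrument`.
#' @param seed integer seed; the same seed always yields the same order.
#' @return character vector of item ids, a permutation of all items.
#' @export
presentation_order <- function(instrument, seed) {
  stopifnot(inherits(instrument, "bs_instrument"))
  ids <- names(instrument$items)
  dims <- vapply(instrument$items, `[[`, "", "dimension")
  withr::with_seed(as.integer(seed), {
    ord <- sample(ids)
    if (length(unique(dims)) > 1L) {
      max_run <- function(o) max(rle(dims[o])$lengths)
      tries <- 0L
      while (max_run(ord) > 3L && tries < 1000L) {
        ord <- sample(ids)
        tries <- tries + 1L
      }
    }
    ord
  })
}

#' Serialise instruments to and from JSON
#'
#' The item banks are published as a versioned JSON document (one object per
#' instrument, items with their option label packs in printed order) so that
#' non-R clients can consume the same bank. `instruments_from_json()` is the
#' inverse: reloading the shipped document reproduces the built-in banks
#' structurally.
#'
#' @param instruments named list of `bs_instrument` objects.
#' @param path file path; for `instruments_to_json` use `NULL` to return the
#'   JSON string instead of writing.
#' @return `instruments_to_json`: the path (or JSON string) invisibly;
#'   `instruments_from_json`: a named list of `bs_instrument`s.
#' @export
instruments_to_json <- function(instruments, path = NULL) {
  doc <- list(
    schema = "burnoutscreen/instruments",
    schema_version = "1",
    instruments = lapply(unname(instruments), function(ins) {
      list(
        id = ins$id,
        version = ins$version,
        items = lapply(unname(ins$items), function(it) {
          it[c("id", "text", "instrument", "dimension", "reverse",
               "options", "alt_options", "answer_pack")]
        })
      )
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' @rdname instruments_to_json
#' @export
instruments_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  out <- lapply(doc$instruments, function(ins) {
    items <- lapply(ins$items, function(it) {
      list(
        id = it$id, text = it$text, instrument = it$instrument,
        dimension = it$dimension, reverse = isTRUE(it$reverse),
        options = as.character(it$options),
        alt_options = if (is.null(it$alt_options)) NULL else
          as.character(it$alt_options),
        answer_pack = it$answer_pack
      )
    })
    names(items) <- vapply(items, `[[`, "", "id")
    structure(list(id = ins$id, version = ins$version, items = items),
              class = "bs_instrument")
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Lifestyle questionnaire profile (stored, never scored)
#'
#' At sign-up the app collects lifestyle context — eating habits, physical
#' activity, and toxic-substance use — that informs psychosocial risk but has
#' no scoring rule. The profile is therefore a passive, validated data type.
#'
#' @param meal_frequency meals per day.
#' @param fruit_veg_servings fruit/vegetable servings per day.
#' @param walking_frequency walking sessions per week.
#' @param activity_minutes minutes per activity session.
#' @param activity_intensity `"none"`, `"moderate"` or `"intensive"`.
#' @param substance_use named list, one entry per substance, each a list with
#'   `used_last_30_days` (logical) and `days_used` (0–30).
#' @return a `bs_lifestyle_profile`.
#' @export
lifestyle_profile <- function(meal_frequency = 3, fruit_veg_servings = 0,
                              walking_frequency = 0, activity_minutes = 0,
                              activity_intensity = c("none", "moderate", "intensive"),
                              substance_use = list()) {
  activity_intensity <- match.arg(activity_intensity)
  counts <- c(meal_frequency = meal_frequency,
              fruit_veg_servings = fruit_veg_servings,
              walking_frequency = walking_frequency,
              activity_minutes = activity_minutes)
  if (any(counts < 0)) {
    bs_abort_validation(sprintf("negative count: %s",
                                names(counts)[counts < 0]), malformed = TRUE)
  }
  for (s in names(substance_use)) {
    d <- substance_use[[s]]$days_used %||% 0
    if (d < 0 || d > 30) {
      bs_abort_validation(sprintf("days_used for %s outside 0..30", s),
                          malformed = TRUE)
    }
  }
  structure(
    list(meal_frequency = meal_frequency,
         fruit_veg_servings = fruit_veg_servings,
         walking_frequency = walking_frequency,
         activity_minutes = activity_minutes,
         activity_intensity = activity_intensity,
         substance_use = substance_use),
    class = "bs_lifestyle_profile"
  )
}
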