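#' Read questionnaire responses from a file
#'
#' Two interchange formats are supported:
#'
#' * **json** — an array of record objects, each with `instrument`,
#'   `respondent_id`, `timestamp` and an `answers` map of item id to option
#'   code or answer label;
#' * **csv** — long format with columns `respondent_id`, `timestamp`,
#'   `instrument`, `item_id`, `answer` (label or code); rows are grouped into
#'   one record per (respondent, instrument, timestamp).
#'
#' Every record is validated against the built-in instrument banks; errors
#' name the offending record (and CSV row) and list all violations found.
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return list of validated `bs_response_record`s (possibly empty, with a
#'   warning for an empty file).
#' @export
read_responses <- function(path, format = c("auto", "json", "csv")) {
  format <- bs_pick_format(match.arg(format), path)
  banks <- load_builtin_instruments()
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.null(raw$instrument)) raw <- list(raw)  # single record object
    if (length(raw) == 0L) {
      warning("no responses in ", path)
      return(list())
    }
    out <- vector("list", length(raw))
    for (i in seq_along(raw)) {
      r <- raw[[i]]
      rec <- tryCatch(
        {
          inst <- banks[[r$instrument %||% ""]]
          if (is.null(inst)) {
            bs_abort_validation(sprintf("unknown instrument: %s",
                                        r$instrument %||% "<missing>"),
                                malformed = TRUE)
          }
          validate_response(inst, response_record(
            r$instrument, r$respondent_id %||% "",
            r$answers %||% list(), r$timestamp %||% Sys.time()
          ))
        },
        bs_validation_error = function(e) {
          bs_abort_validation(
            c(sprintf("record %d:", i), e$violations),
            incomplete = e$incomplete, malformed = e$malformed
          )
        }
      )
      out[[i]] <- rec
    }
    return(out)
  }
  df <- utils::read.csv(path, colClasses = "character")
  needed <- c("respondent_id", "timestamp", "instrument", "item_id", "answer")
  if (!all(needed %in% names(df))) {
    bs_abort_validation(sprintf("missing column: %s", setdiff(needed, names(df))),
                        malformed = TRUE)
  }
  if (nrow(df) == 0L) {
    warning("no responses in ", path)
    return(list())
  }
  df$.row <- seq_len(nrow(df)) + 1L  # file row, counting the header
  key <- paste(df$respondent_id, df$instrument, df$timestamp, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- df[key == k, ]
    inst <- banks[[rows$instrument[[1]]]]
    if (is.null(inst)) {
      bs_abort_validation(
        sprintf("row %d: unknown instrument '%s'", rows$.row[[1]],
                rows$instrument[[1]]),
        malformed = TRUE
      )
    }
    bad <- !(rows$item_id %in% names(inst$items))
    if (any(bad)) {
      bs_abort_validation(
        sprintf("row %d: unknown item id '%s'", rows$.row[bad],
                rows$item_id[bad]),
        malformed = TRUE
      )
    }
    ans <- as.list(rows$answer)
    # bare digits are ordinal codes, anything else an answer label
    ans <- lapply(ans, function(a) if (grepl("^[0-9]+$", a)) as.integer(a) else a)
    names(ans) <- rows$item_id
    out[[length(out) + 1L]] <- validate_response(inst, response_record(
      rows$instrument[[1]], rows$respondent_id[[1]], ans, rows$timestamp[[1]]
    ))
  }
  out
}

#' Write response records to a file
#'
#' Inverse of [read_responses()]: emits the same JSON or long-CSV dialect.
#'
#' @param records list of `bs_response_record`s.
#' @param path output file path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path, format = c("auto", "json", "csv")) {
  format <- bs_pick_format(match.arg(format), path)
  if (format == "json") {
    doc <- lapply(records, function(r) list(
      instrument = r$instrument_id,
      respondent_id = r$respondent_id,
      timestamp = bs_format_timestamp(r$timestamp),
      answers = r$answers
    ))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      respondent_id = r$respondent_id,
      timestamp = bs_format_timestamp(r$timestamp),
      instrument = r$instrument_id,
      item_id = names(r$answers),
      answer = vapply(r$answers, as.character, ""),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

bs_pick_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
}

# --- test-record (scored result) serialisation --------------------------------

bs_record_to_list <- function(r) {
  list(
    respondent_id = r$respondent_id,
    timestamp = bs_format_timestamp(r$timestamp),
    ghq = list(score = r$ghq$score, threshold = r$ghq$threshold,
               distress = r$ghq$distress, standard_band = r$ghq$standard_band),
    cbi = list(
      personal = r$cbi$personal[c("dimension", "score", "level")],
      work = r$cbi$work[c("dimension", "score", "level")],
      client = r$cbi$client[c("dimension", "score", "level")],
      overall_risk = r$cbi$overall_risk
    ),
    diagnosis = list(category = r$diagnosis$category,
                     rationale = r$diagnosis$rationale)
  )
}

bs_record_from_list <- function(x) {
  dims <- lapply(x$cbi[c("personal", "work", "client")], function(d) {
    structure(list(dimension = d$dimension, score = as.numeric(d$score),
                   level = d$level),
              class = "bs_dimension_score")
  })
  structure(
    list(
      respondent_id = x$respondent_id,
      timestamp = bs_parse_timestamp(x$timestamp),
      ghq = new_ghq_result(as.integer(x$ghq$score), as.integer(x$ghq$threshold)),
      cbi = structure(c(dims, list(overall_risk = x$cbi$overall_risk)),
                      class = "bs_cbi_result"),
      diagnosis = new_diagnosis(x$diagnosis$category, x$diagnosis$rationale)
    ),
    class = "bs_test_record"
  )
}

#' Write scored test records to a file
#'
#' JSON keeps the full nested structure and round-trips exactly through
#' [read_results()]; CSV flattens to one row per record (scores at 2-decimal
#' precision) with columns `respondent_id`, `timestamp`, `ghq_score`,
#' `ghq_distress`, `ghq_band`, `personal`, `work`, `client`, the three
#' `*_level` columns, `overall_risk` and `category`.
#'
#' @param records list of `bs_test_record`s.
#' @param path output file path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("auto", "json", "csv")) {
  format <- bs_pick_format(match.arg(format), path)
  if (inherits(records, "bs_test_record")) records <- list(records)
  if (format == "json") {
    doc <- list(schema = "burnoutscreen/results", schema_version = "1",
                records = lapply(records, bs_record_to_list))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      respondent_id = r$respondent_id,
      timestamp = bs_format_timestamp(r$timestamp),
      ghq_score = r$ghq$score,
      ghq_threshold = r$ghq$threshold,
      ghq_distress = r$ghq$distress,
      ghq_band = r$ghq$standard_band,
      personal = sprintf("%.2f", r$cbi$personal$score),
      work = sprintf("%.2f", r$cbi$work$score),
      client = sprintf("%.2f", r$cbi$client$score),
      personal_level = r$cbi$personal$level,
      work_level = r$cbi$work$level,
      client_level = r$cbi$client$level,
      overall_risk = r$cbi$overall_risk,
      category = r$diagnosis$category,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @return `read_results()`: list of `bs_test_record`s.
#' @export
read_results <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc$records, bs_record_from_list)
}

#' Persist and reload a monitoring history
#'
#' Histories are stored as a versioned JSON document (respondent id plus an
#' array of scored test records); `read_history(write_history(h))` is the
#' identity.
#'
#' @param history a `bs_history`.
#' @param path file path.
#' @return `write_history`: `path` invisibly; `read_history`: a `bs_history`.
#' @export
write_history <- function(history, path) {
  stopifnot(inherits(history, "bs_history"))
  doc <- list(schema = "burnoutscreen/history", schema_version = "1",
              respondent_id = history$respondent_id,
              records = lapply(history$records, bs_record_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  new_history(doc$respondent_id, lapply(doc$records, bs_record_from_list))
}

#' Run configuration
#'
#' Engine-level settings with defaults reproducing the screening app's
#' behaviour: GHQ distress threshold 3 and a 3-month retest interval.
#' Settings may be loaded from a JSON or YAML file.
#'
#' @param path optional JSON/YAML file; missing keys fall back to defaults.
#' @param ghq_threshold integer 0..12.
#' @param retest_interval_months positive integer.
#' @param output_format `"json"` or `"csv"`.
#' @param log_level one of `"quiet"`, `"info"`, `"debug"`.
#' @return a `bs_run_config` list.
#' @export
run_config <- function(path = NULL, ghq_threshold = 3L,
                       retest_interval_months = 3L,
                       output_format = c("json", "csv"),
                       log_level = c("info", "quiet", "debug")) {
  output_format <- match.arg(output_format)
  log_level <- match.arg(log_level)
  cfg <- list(ghq_threshold = as.integer(ghq_threshold),
              retest_interval_months = as.integer(retest_interval_months),
              output_format = output_format, log_level = log_level)
  if (!is.null(path)) {
    loaded <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required to read YAML config")
      }
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    }
    for (k in intersect(names(loaded), names(cfg))) cfg[[k]] <- loaded[[k]]
    cfg$ghq_threshold <- as.integer(cfg$ghq_threshold)
    cfg$retest_interval_months <- as.integer(cfg$retest_interval_months)
  }
  if (cfg$ghq_threshold < 0L || cfg$ghq_threshold > 12L) {
    bs_abort_validation("ghq_threshold must be in 0..12", malformed = TRUE)
  }
  if (cfg$retest_interval_months < 0L) {
    bs_abort_validation("retest_interval_months must be >= 0", malformed = TRUE)
  }
  structure(cfg, class = "bs_run_config")
}
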