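test_that("built-in banks match the published instruments structurally", {
  expect_length(ghq_bank$items, 12)
  expect_true(all(vapply(ghq_bank$items, function(it) length(it$options), 0L) == 4L))
  expect_true(all(vapply(ghq_bank$items, `[[`, "", "dimension") == "none"))
  expect_false(any(vapply(ghq_bank$items, `[[`, NA, "reverse")))

  expect_length(cbi_bank$items, 19)
  dims <- vapply(cbi_bank$items, `[[`, "", "dimension")
  expect_equal(sum(dims == "personal"), 6)
  expect_equal(sum(dims == "work"), 7)
  expect_equal(sum(dims == "client"), 6)
  expect_true(all(vapply(cbi_bank$items, function(it) length(it$options), 0L) == 5L))

  # exactly one reverse item, the work-dimension energy question
  rev <- vapply(cbi_bank$items, `[[`, NA, "reverse")
  expect_equal(sum(rev), 1)
  rev_item <- cbi_bank$items[[names(rev)[rev]]]
  expect_equal(rev_item$dimension, "work")
  expect_match(rev_item$text, "enough energy")

  # ids unique within each instrument
  expect_equal(anyDuplicated(names(ghq_bank$items)), 0)
  expect_equal(anyDuplicated(names(cbi_bank$items)), 0)

  # idempotent
  expect_identical(load_builtin_instruments(), banks)
})

test_that("JSON round-trip reproduces the banks structurally", {
  path <- withr::local_tempfile(fileext = ".json")
  instruments_to_json(banks, path)
  reloaded <- instruments_from_json(path)
  expect_identical(reloaded$GHQ12$items, ghq_bank$items)
  expect_identical(reloaded$CBI$items, cbi_bank$items)
  # the shipped document is the same bank
  shipped <- instruments_from_json(
    system.file("extdata", "instruments.json", package = "burnoutscreen")
  )
  expect_identical(shipped$CBI$items, cbi_bank$items)
  expect_identical(shipped$GHQ12$items, ghq_bank$items)
})

test_that("validate_response accepts complete records and normalises labels", {
  rec <- cbi_record(rep(0L, 19))
  expect_identical(validate_response(cbi_bank, rec)$answers, rec$answers)

  # labels from either CBI answer pack resolve to the same codes
  by_label1 <- response_record("CBI", "r1",
    setNames(rep("Sometimes", 19), names(cbi_bank$items)), "2022-01-15")
  by_label2 <- response_record("CBI", "r1",
    setNames(rep("Somewhat", 19), names(cbi_bank$items)), "2022-01-15")
  expect_identical(validate_response(cbi_bank, by_label1)$answers,
                   validate_response(cbi_bank, by_label2)$answers)
  expect_equal(validate_response(cbi_bank, by_label1)$answers[["cbi.per.q1"]], 2L)

  # GHQ labels use the item's own printed wording
  ghq_lab <- response_record("GHQ12", "r1", c(
    ghq.q01 = "Better than usual", ghq.q02 = "Not at all",
    ghq.q03 = "More useful than usual", ghq.q04 = "More than usual",
    ghq.q05 = "Not at all", ghq.q06 = "Not at all",
    ghq.q07 = "More than usual", ghq.q08 = "More capable than usual",
    ghq.q09 = "Not at all", ghq.q10 = "Not at all",
    ghq.q11 = "Not at all", ghq.q12 = "More than usual"), "2022-01-15")
  expect_equal(score_ghq(ghq_lab)$score, 0)
})

test_that("validate_response reports every violation in one pass", {
  # one missing answer -> incomplete, names the item
  partial <- ghq_record(0L)
  partial$answers[["ghq.q07"]] <- NULL
  err <- tryCatch(validate_response(ghq_bank, partial), condition = identity)
  expect_s3_class(err, "bs_validation_error")
  expect_true(err$incomplete)
  expect_false(err$malformed)
  expect_match(err$violations, "ghq.q07", all = FALSE)

  # out-of-range code -> malformed
  bad <- cbi_record(0L)
  bad$answers[["cbi.per.q1"]] <- 7L
  err <- tryCatch(validate_response(cbi_bank, bad), condition = identity)
  expect_true(err$malformed)
  expect_false(err$incomplete)

  # unknown item + missing item + bad code all reported together
  messy <- cbi_record(0L)
  messy$answers[["cbi.per.q1"]] <- NULL
  messy$answers[["made.up"]] <- 1L
  messy$answers[["cbi.cli.q2"]] <- "nonsense"
  err <- tryCatch(validate_response(cbi_bank, messy), condition = identity)
  expect_true(err$incomplete && err$malformed)
  expect_length(err$violations, 3)

  # wrong instrument id
  expect_error(validate_response(ghq_bank, cbi_record(0L)),
               class = "bs_validation_error")
})

test_that("presentation_order is a seeded permutation with mixed dimensions", {
  expect_identical(presentation_order(cbi_bank, 1),
                   presentation_order(cbi_bank, 1))
  for (seed in c(1, 7, 123)) {
    ord <- presentation_order(ghq_bank, seed)
    expect_setequal(ord, names(ghq_bank$items))
    expect_length(ord, 12)
  }
  # CBI orders interleave dimensions: no run of >3 same-dimension items
  dims <- vapply(cbi_bank$items, `[[`, "", "dimension")
  for (seed in 1:25) {
    ord <- presentation_order(cbi_bank, seed)
    expect_setequal(ord, names(cbi_bank$items))
    expect_lte(max(rle(dims[ord])$lengths), 3)
  }
  # different seeds give different orders (>= 99 of 100 pairs)
  differs <- vapply(1:100, function(i) {
    !identical(presentation_order(cbi_bank, 2 * i),
               presentation_order(cbi_bank, 2 * i + 1))
  }, NA)
  expect_gte(sum(differs), 99)
})

test_that("lifestyle profile stores but rejects impossible values", {
  p <- lifestyle_profile(meal_frequency = 3, fruit_veg_servings = 2,
                         activity_intensity = "moderate",
                         substance_use = list(alcohol = list(
                           used_last_30_days = TRUE, days_used = 4)))
  expect_s3_class(p, "bs_lifestyle_profile")
  expect_error(lifestyle_profile(meal_frequency = -1),
               class = "bs_validation_error")
  expect_error(
    lifestyle_profile(substance_use = list(x = list(days_used = 31))),
    class = "bs_validation_error"
  )
})
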