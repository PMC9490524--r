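test_that("simulators are deterministic per seed and emit valid records", {
  prof <- respondent_profile()
  expect_identical(simulate_ghq(prof, 5), simulate_ghq(prof, 5))
  expect_identical(simulate_cbi(prof, 5), simulate_cbi(prof, 5))
  expect_identical(simulate_sus(prof, 5), simulate_sus(prof, 5))
  expect_false(identical(simulate_cbi(prof, 5)$answers,
                         simulate_cbi(prof, 6)$answers))
  # every emitted record passes validation against its bank
  for (s in 1:25) {
    expect_silent(validate_response(ghq_bank, simulate_ghq(prof, s)))
    expect_silent(validate_response(cbi_bank, simulate_cbi(prof, s)))
  }
})

test_that("degenerate GHQ profiles hit the scale ends", {
  lo <- respondent_profile(ghq_negativity = 0)
  hi <- respondent_profile(ghq_negativity = 1)
  for (s in 1:10) {
    expect_equal(score_ghq(simulate_ghq(lo, s))$score, 0)
    expect_equal(score_ghq(simulate_ghq(hi, s))$score, 12)
  }
})

test_that("GHQ totals at negativity 0.5 average 6.0 +/- 0.2 over 2,000 draws", {
  prof <- respondent_profile(ghq_negativity = 0.5)
  scores <- vapply(1:2000, function(s) score_ghq(simulate_ghq(prof, s))$score, 0)
  expect_equal(mean(scores), 6.0, tolerance = 0.2 / 6.0)
  expect_gte(min(scores), 0)
  expect_lte(max(scores), 12)
})

test_that("noise-free CBI simulation recovers the target level off boundaries", {
  zero <- respondent_profile(cbi_target = c(personal = 0, work = 0, client = 0),
                             cbi_noise = 0)
  full <- respondent_profile(cbi_target = c(personal = 100, work = 100,
                                            client = 100), cbi_noise = 0)
  for (s in 1:5) {
    r0 <- score_cbi(simulate_cbi(zero, s))
    expect_equal(r0$overall_risk, "low")
    expect_equal(status_message(make_record(
      simulate_ghq(respondent_profile(ghq_negativity = 0), s),
      simulate_cbi(zero, s)
    )), "congratulations")
    expect_equal(score_cbi(simulate_cbi(full, s))$overall_risk, "high")
  }
  # targets away from the cut-offs by more than 25/(2n) recover exactly
  targets <- c(5, 10, 20, 30, 40, 45, 55, 60, 65, 70, 80, 90, 95, 100)
  for (t in targets) {
    prof <- respondent_profile(cbi_target = c(personal = t, work = t,
                                              client = t), cbi_noise = 0)
    for (s in c(1, 17)) {
      res <- score_cbi(simulate_cbi(prof, s))
      for (d in c("personal", "work", "client")) {
        expect_equal(res[[d]]$level, classify_level(t),
                     info = sprintf("target %g dim %s seed %d", t, d, s))
      }
    }
  }
})

test_that("moderate targets with noise stay moderate overall (>=90% of 500 seeds)", {
  prof <- respondent_profile(cbi_target = c(personal = 60, work = 60,
                                            client = 60), cbi_noise = 0.5)
  risks <- vapply(1:500, function(s)
    score_cbi(simulate_cbi(prof, s))$overall_risk, "")
  expect_gte(mean(risks == "moderate"), 0.90)
})

test_that("simulate_history composes records at successive due dates", {
  mk <- function(t, neg) respondent_profile(
    ghq_negativity = neg,
    cbi_target = c(personal = t, work = t, client = t),
    cbi_noise = 0
  )
  profiles <- list(mk(90, 1), mk(60, 0.5), mk(40, 0), mk(10, 0))
  h <- simulate_history(profiles, start = as.Date("2022-01-01"),
                        interval_months = 3, seed = 11)
  expect_length(h$records, 4)
  dates <- as.Date(vapply(h$records, function(r)
    format(r$timestamp, "%Y-%m-%d", tz = "UTC"), ""))
  expect_equal(dates, as.Date(c("2022-01-01", "2022-04-01",
                                "2022-07-01", "2022-10-01")))
  series <- recent_diagnoses(h)
  expect_equal(series$overall_risk, c("high", "moderate", "low", "low"))
  # improving targets show as improving deltas at noise 0
  expect_true(all(dimension_deltas(h)$trend == "improved"))
  # reproducible end to end
  expect_identical(h, simulate_history(profiles, start = as.Date("2022-01-01"),
                                       interval_months = 3, seed = 11))
  # single profile: downstream insufficient-history behaviour
  h1 <- simulate_history(profiles[1], seed = 3)
  expect_error(dimension_deltas(h1), class = "bs_validation_error")
})
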