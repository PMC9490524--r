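test_that("answer values are 100/75/50/25/0, inverted for the reverse item", {
  fwd <- cbi_bank$items$cbi.per.q1
  rev <- cbi_bank$items$cbi.wrk.q7
  expect_true(rev$reverse)
  for (code in 0:4) {
    expect_equal(code_cbi_answer(fwd, code), 25 * (4 - code))
    # reverse-item identity: coded value = 100 - forward-coded value
    expect_equal(code_cbi_answer(rev, code), 100 - code_cbi_answer(fwd, code))
  }
  expect_equal(code_cbi_answer(fwd, "Always"), 100)
  expect_equal(code_cbi_answer(fwd, "To a very high degree"), 100)
  expect_equal(code_cbi_answer(fwd, "Never or almost never"), 0)
  expect_equal(code_cbi_answer(rev, "Always"), 0)
  expect_error(code_cbi_answer(fwd, 7), class = "bs_validation_error")
  expect_error(code_cbi_answer(ghq_bank$items$ghq.q01, 0),
               class = "bs_validation_error")
})

test_that("dimension score is the mean of its items' values", {
  # personal all "Always" -> 100, high
  d <- score_dimension(cbi_record(0L), "personal")
  expect_equal(d$score, 100)
  expect_equal(d$level, "high")

  # work: six items "Never or almost never", reverse item "Always" -> 0, low
  codes <- setNames(rep(4L, 19), names(cbi_bank$items))
  codes[["cbi.wrk.q7"]] <- 0L
  d <- score_dimension(cbi_record(unname(codes)), "work")
  expect_equal(d$score, 0)
  expect_equal(d$level, "low")

  # personal values (100,75,50,25,0,50) -> mean 50, moderate
  codes <- setNames(rep(4L, 19), names(cbi_bank$items))
  codes[paste0("cbi.per.q", 1:6)] <- c(0L, 1L, 2L, 3L, 4L, 2L)
  d <- score_dimension(cbi_record(unname(codes)), "personal")
  expect_equal(d$score, 50)
  expect_equal(d$level, "moderate")
})

test_that("dimension score is invariant to answer order within the dimension", {
  withr::local_seed(99)
  for (i in 1:20) {
    vals <- sample(0:4, 6, replace = TRUE)
    codes <- setNames(rep(0L, 19), names(cbi_bank$items))
    codes[paste0("cbi.cli.q", 1:6)] <- vals
    base <- score_dimension(cbi_record(unname(codes)), "client")$score
    codes[paste0("cbi.cli.q", 1:6)] <- sample(vals)
    expect_equal(score_dimension(cbi_record(unname(codes)), "client")$score,
                 base)
  }
})

test_that("level boundaries sit at 50 and 75", {
  expect_equal(classify_level(0), "low")
  expect_equal(classify_level(49.99), "low")
  expect_equal(classify_level(50), "moderate")
  expect_equal(classify_level(74.99), "moderate")
  expect_equal(classify_level(75), "high")
  expect_equal(classify_level(100), "high")
  expect_error(classify_level(-1), class = "bs_validation_error")
  expect_error(classify_level(101), class = "bs_validation_error")
})

test_that("no attainable 6-item mean lies strictly between 74 and 75", {
  sums <- 25 * (0:24)                # attainable item-value sums, step 25
  means <- unique(sums / 6)
  expect_false(any(means > 74 & means < 75))
  # nearest attainable means around the gap
  expect_true(max(means[means < 75]) <= 74 + 1e-9)
})

test_that("combine_risk reproduces the published risk table and its completion", {
  # printed cases
  expect_equal(combine_risk(c("low", "low", "low")), "low")
  expect_equal(combine_risk(c("low", "low", "moderate")), "low")
  expect_equal(combine_risk(c("moderate", "moderate", "moderate")), "moderate")
  expect_equal(combine_risk(c("moderate", "moderate", "low")), "moderate")
  expect_equal(combine_risk(c("moderate", "moderate", "high")), "moderate")
  expect_equal(combine_risk(c("high", "high", "low")), "high")
  expect_equal(combine_risk(c("high", "high", "moderate")), "high")
  expect_equal(combine_risk(c("high", "high", "high")), "high")
  # unprinted single-high cases resolve to moderate, never low
  expect_equal(combine_risk(c("low", "low", "high")), "moderate")
  expect_equal(combine_risk(c("low", "moderate", "high")), "moderate")
})

test_that("combine_risk is total, permutation-invariant and monotone (27 cells)", {
  rank <- function(l) match(l, all_levels)
  grid <- expand.grid(a = all_levels, b = all_levels, c = all_levels,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    lv <- unlist(grid[i, ])
    out <- combine_risk(lv)
    expect_true(out %in% all_levels)
    expect_equal(combine_risk(rev(lv)), out)
    expect_equal(combine_risk(sample(lv)), out)
    # upgrading any one dimension never lowers the overall risk
    for (j in 1:3) {
      if (rank(lv[[j]]) < 3) {
        up <- lv
        up[[j]] <- all_levels[[rank(lv[[j]]) + 1L]]
        expect_gte(rank(combine_risk(up)), rank(out))
      }
    }
  }
  expect_error(combine_risk(c("low", "low")), class = "bs_validation_error")
  expect_error(combine_risk(c("low", "low", "extreme")),
               class = "bs_validation_error")
})

test_that("full CBI scoring composes subscales and overall risk", {
  # all "Always": personal/client 100, work (6*100 + 0)/7 via the reverse item
  res <- score_cbi(cbi_record(0L))
  expect_equal(res$personal$score, 100)
  expect_equal(res$work$score, 600 / 7, tolerance = 1e-12)
  expect_equal(res$client$score, 100)
  expect_equal(res$overall_risk, "high")

  # all "Never or almost never": work gets 100/7 from the reverse item
  res <- score_cbi(cbi_record(4L))
  expect_equal(res$personal$score, 0)
  expect_equal(res$work$score, 100 / 7, tolerance = 1e-12)
  expect_equal(res$client$score, 0)
  expect_equal(res$overall_risk, "low")

  # personal high, work high, client low -> overall high
  res <- score_cbi(cbi_record_points(100, 100, 0))
  expect_equal(vapply(res[c("personal", "work", "client")], `[[`, "", "level"),
               c(personal = "high", work = "high", client = "low"))
  expect_equal(res$overall_risk, "high")
})
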