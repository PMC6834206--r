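test_that("PHQ-9 totals, categories, and the major-depression flag", {
  zero <- score_phq9(rep(0, 9))
  expect_equal(zero$total, 0)
  expect_equal(zero$category, "minimal")
  expect_false(zero$major_depression_flag)

  top <- score_phq9(rep(3, 9))
  expect_equal(top$total, 27)
  expect_equal(top$category, "severe")
  expect_true(top$major_depression_flag)

  ten <- score_phq9(c(3, 3, 2, 2, 0, 0, 0, 0, 0))
  expect_equal(ten$total, 10)
  expect_equal(ten$category, "moderate")
  expect_true(ten$major_depression_flag)
  expect_false(ten$higher_is_better)

  expect_error(score_phq9(rep(0, 8)), "9 items")
  expect_error(score_phq9(c(rep(0, 8), 4)), "item 9")
})

test_that("PHQ-9 category is a step function with breakpoints 5/10/15/20", {
  set.seed(21)
  cat_of <- function(total) {
    # build any legal vector with that total
    v <- rep(3, total %/% 3)
    if (total %% 3 > 0) v <- c(v, total %% 3)
    score_phq9(c(v, rep(0, 9 - length(v))))
  }
  want <- function(total) {
    if (total <= 4) "minimal" else if (total <= 9) "mild"
    else if (total <= 14) "moderate" else if (total <= 19) "moderately severe"
    else "severe"
  }
  for (total in 0:27) {
    s <- cat_of(total)
    expect_equal(s$category, want(total), info = paste("total", total))
    expect_equal(s$major_depression_flag, total >= 10)
    expect_gte(s$total, 0); expect_lte(s$total, 27)
  }
})

test_that("sum-based instruments score by addition within their ranges", {
  expect_equal(score_simple_sum("AHFKT", rep(1, 30))$total, 30)
  expect_true(score_simple_sum("AHFKT", rep(1, 30))$higher_is_better)
  expect_equal(score_simple_sum("FSSQ", rep(5, 8))$total, 40)
  expect_equal(score_simple_sum("FSSQ", rep(1, 8))$total, 8)
  expect_equal(score_simple_sum("CIRS", rep(0, 14))$total, 0)
  expect_equal(score_simple_sum("CIRS", rep(4, 14))$total, 56)
  expect_false(score_simple_sum("CIRS", rep(0, 14))$higher_is_better)
  expect_error(score_simple_sum("AHFKT", rep(2, 30)), "item 1")
  expect_error(score_simple_sum("FSSQ", rep(5, 7)), "8 items")
})

test_that("instrument totals stay in range and are monotone per item", {
  set.seed(22)
  specs <- list(
    list(f = score_phq9, n = 9, lo = 0, hi = 3, min = 0, max = 27),
    list(f = function(v) score_simple_sum("AHFKT", v), n = 30, lo = 0, hi = 1,
         min = 0, max = 30),
    list(f = function(v) score_simple_sum("CIRS", v), n = 14, lo = 0, hi = 4,
         min = 0, max = 56),
    list(f = function(v) score_simple_sum("FSSQ", v), n = 8, lo = 1, hi = 5,
         min = 8, max = 40)
  )
  for (sp in specs) {
    for (rep in 1:25) {
      v <- sample(sp$lo:sp$hi, sp$n, replace = TRUE)
      total <- sp$f(v)$total
      expect_gte(total, sp$min); expect_lte(total, sp$max)
      i <- sample(sp$n, 1)
      if (v[i] < sp$hi) {
        v2 <- v; v2[i] <- v2[i] + 1
        expect_gte(sp$f(v2)$total, total)   # raising an item never lowers it
      }
    }
  }
})

test_that("MMAS-8 counts non-adherence points, lower is better", {
  best <- score_mmas8(rep(0, 8))
  expect_equal(best$total, 0)
  expect_false(best$higher_is_better)
  expect_equal(score_mmas8(c(rep(1, 7), 4))$total, 8)
  expect_equal(score_mmas8(c(1, 1, 1, 0, 0, 0, 0, 0))$total, 3)
  expect_equal(score_mmas8(c(rep(0, 7), 2))$total, 0.5)  # item-8 frequency map
  expect_error(score_mmas8(rep(0, 7)), "8 items")
  expect_error(score_mmas8(c(rep(2, 7), 0)), "item 1")
})

test_that("SCHFI subscales are raw sums with an optional standardization", {
  floor_m <- score_schfi("maintenance", rep(1, 10))
  expect_equal(floor_m$total, 10)
  expect_true(floor_m$higher_is_better)
  expect_equal(score_schfi("confidence", rep(4, 6))$total, 24)
  # additivity: one item up by one -> total up by one
  v <- c(2, 3, 1, 4, 2, 2, 3, 1, 2, 3)
  v2 <- v; v2[4] <- 3
  expect_equal(score_schfi("maintenance", v)$total - 1,
               score_schfi("maintenance", v2)$total)
  # a raw maintenance total near 23 is representable without clipping
  expect_silent(score_schfi("maintenance", c(2, 2, 2, 2, 2, 2, 3, 3, 2, 3)))
  expect_equal(score_schfi("management", rep(1, 6), standardize = TRUE)$total, 0)
  expect_equal(score_schfi("management", rep(4, 6), standardize = TRUE)$total, 100)
  expect_error(score_schfi("wellness", rep(1, 6)))
})

test_that("KCCQ domain scores span 0-100 and honor the half-missing rule", {
  best <- score_kccq(rep(5, 23))
  expect_equal(best$total, 100)
  expect_equal(best$physical_limitation, 100)
  expect_equal(best$self_efficacy, 100)
  worst <- score_kccq(rep(1, 23))
  expect_equal(worst$total, 0)
  expect_equal(worst$symptoms, 0)

  # physical-limitation domain (items 1-6): three answered of six ->
  # mean-of-answered, matching a hand recomputation
  v <- rep(3, 23)
  v[1:3] <- NA
  v[4:6] <- c(2, 4, 5)
  s <- score_kccq(v)
  expect_equal(s$physical_limitation, 100 * (mean(c(2, 4, 5)) - 1) / 4)

  # more than half missing -> domain NA, others still computed
  v2 <- rep(3, 23)
  v2[1:4] <- NA
  s2 <- score_kccq(v2)
  expect_true(is.na(s2$physical_limitation))
  expect_false(is.na(s2$symptoms))
  expect_error(score_kccq(rep(6, 23)), "out of range")
  expect_error(score_kccq(rep(3, 20)), "23 items")
})

test_that("long-format response tables dispatch to the right scorers", {
  resp <- dplyr::bind_rows(
    tibble::tibble(respondent_id = "r1", instrument_id = "PHQ9",
                   item_index = 1:9, value = c(3, 3, 2, 2, 0, 0, 0, 0, 0)),
    tibble::tibble(respondent_id = "r1", instrument_id = "FSSQ",
                   item_index = 1:8, value = rep(5, 8)),
    tibble::tibble(respondent_id = "r2", instrument_id = "SCHFI_MAINT",
                   item_index = 1:10, value = rep(2, 10))
  )
  out <- score_responses(resp)
  expect_equal(nrow(out), 3)
  expect_equal(out$total[out$instrument_id == "PHQ9"], 10)
  expect_equal(out$total[out$instrument_id == "FSSQ"], 40)
  expect_equal(out$total[out$instrument_id == "SCHFI"], 20)
  expect_error(score_responses(dplyr::mutate(resp, instrument_id = "XXX")),
               "unknown instrument")
})

test_that("eligibility gate flags each failed criterion by name", {
  p <- eligible_profile_template()
  expect_true(check_eligibility(p)$eligible)
  expect_length(check_eligibility(p)$failed_criteria, 0)

  p_moca <- p; p_moca$moca_total <- 19
  v <- check_eligibility(p_moca)
  expect_false(v$eligible)
  expect_equal(v$failed_criteria, "moca")

  p_age <- p; p_age$age <- 29
  expect_equal(check_eligibility(p_age)$failed_criteria, "age")

  p_nyha <- p; p_nyha$nyha_class <- "I"
  expect_equal(check_eligibility(p_nyha)$failed_criteria, "nyha_class")

  p_vision <- p; p_vision$visual_acuity_denominator <- 70
  expect_equal(check_eligibility(p_vision)$failed_criteria, "vision")

  p_missing <- p; p_missing$hearing_pass <- NULL
  expect_error(check_eligibility(p_missing), "hearing_pass")
})

test_that("eligibility equals a brute-force conjunction over boolean criteria", {
  # 10 boolean criteria: 4 inclusion-style (fail when FALSE) and 6 exclusions
  inclusion <- c("hearing_pass", "speaks_english",
                 "recent_hf_hospitalization", "willing_to_use_app")
  exclusion <- c("transplant_1a_or_inotrope", "palliative_hospice",
                 "stroke_past_year", "aphasia_major_disability",
                 "uncontrolled_psychiatric", "dependent_living")
  fields <- c(inclusion, exclusion)
  id_of <- c(hearing_pass = "hearing", speaks_english = "english",
             recent_hf_hospitalization = "recent_hf_hospitalization",
             willing_to_use_app = "willing",
             setNames(exclusion, exclusion))
  for (mask in 0:(2^10 - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:9)))
    p <- eligible_profile_template()
    for (k in seq_along(fields)) {
      f <- fields[k]
      # bit TRUE means "this criterion is violated"
      p[[f]] <- if (f %in% inclusion) !bits[k] else bits[k]
    }
    v <- check_eligibility(p)
    expect_equal(v$eligible, !any(bits))
    expect_setequal(v$failed_criteria, unname(id_of[fields[bits]]))
  }
})
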