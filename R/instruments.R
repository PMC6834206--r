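#' @title Patient-reported outcome instrument scoring
#' @description
#' Scorers for the study battery. Each scorer validates its item vector
#' against the instrument definition (count and legal range, reporting the
#' offending item index), computes the total and any subscales, and records
#' the instrument's direction of benefit (`higher_is_better`): higher is
#' better for HF knowledge (AHFKT), self-care (SCHFI), quality of life
#' (KCCQ), and social support (FSSQ); lower is better for depression
#' (PHQ-9), non-adherence points (MMAS-8), and illness burden (CIRS).
#' @name instrument-scoring
NULL

check_items <- function(responses, n, lo, hi, instrument,
                        integer_only = TRUE) {
  if (length(responses) != n) {
    abort(sprintf("%s requires exactly %d items (got %d)",
                  instrument, n, length(responses)))
  }
  ok <- is.finite(responses) & responses >= lo & responses <= hi
  if (integer_only) ok <- ok & responses == round(responses)
  if (!all(ok)) {
    abort(sprintf("%s item %d is out of range [%s, %s]: %s",
                  instrument, which(!ok)[1], lo, hi,
                  deparse(responses[which(!ok)[1]])))
  }
  invisible(responses)
}

score_row <- function(instrument_id, total, higher_is_better,
                      category = NA_character_, ...) {
  tibble::tibble(instrument_id = instrument_id, total = total,
                 category = category, higher_is_better = higher_is_better,
                 ...)
}

#' Score the PHQ-9 depression scale
#'
#' Nine items, each 0 (not at all) to 3 (nearly every day); total 0–27 with
#' severity cutpoints at 5, 10, 15, and 20 (minimal / mild / moderate /
#' moderately severe / severe) and a probable-major-depression flag at a
#' total of 10 or more. Higher scores mean worse depression.
#'
#' @param responses Integer vector of 9 items, each in 0..3.
#' @return A one-row tibble: `instrument_id`, `total`, `category`,
#'   `higher_is_better` (`FALSE`), `major_depression_flag`.
#' @examples
#' score_phq9(c(3, 3, 2, 2, 0, 0, 0, 0, 0))
#' @export
score_phq9 <- function(responses) {
  check_items(responses, 9, 0, 3, "PHQ-9")
  total <- sum(responses)
  category <- as.character(cut(
    total, breaks = c(-Inf, 4, 9, 14, 19, Inf),
    labels = c("minimal", "mild", "moderate", "moderately severe", "severe")
  ))
  score_row("PHQ9", total, FALSE, category,
            major_depression_flag = total >= 10)
}

#' Score sum-based instruments (AHFKT, FSSQ, CIRS)
#'
#' Simple additive totals: the Atlanta Heart Failure Knowledge Test (30
#' items keyed correct = 1 / incorrect = 0, total 0–30, higher is better);
#' the Duke-UNC Functional Social Support Questionnaire (8 items on a
#' 5-point Likert scale 1–5, total 8–40, higher is better); and the
#' Cumulative Illness Rating Scale (14 organ systems rated 0–4, total 0–56,
#' higher means more illness burden).
#'
#' @param instrument_id One of `"AHFKT"`, `"FSSQ"`, `"CIRS"`.
#' @param responses Item vector conforming to the instrument definition.
#' @return A one-row tibble (see [score_phq9()] for the shape).
#' @export
score_simple_sum <- function(instrument_id, responses) {
  instrument_id <- match.arg(toupper(instrument_id),
                             c("AHFKT", "FSSQ", "CIRS"))
  spec <- switch(instrument_id,
    AHFKT = list(n = 30, lo = 0, hi = 1, higher = TRUE),
    FSSQ  = list(n = 8,  lo = 1, hi = 5, higher = TRUE),
    CIRS  = list(n = 14, lo = 0, hi = 4, higher = FALSE)
  )
  check_items(responses, spec$n, spec$lo, spec$hi, instrument_id)
  score_row(instrument_id, sum(responses), spec$higher)
}

#' Key raw AHFKT answers against an answer map
#'
#' Converts a vector of raw multiple-choice answers to correct (1) /
#' incorrect (0) item scores using a keyed answer map, ready for
#' [score_simple_sum()].
#'
#' @param answers Character vector of 30 chosen options.
#' @param key Character vector of 30 correct options.
#' @return Integer vector of 0/1 item scores.
#' @export
key_ahfkt <- function(answers, key) {
  if (length(answers) != length(key)) {
    abort("answers and key must have the same length")
  }
  as.integer(answers == key)
}

#' Score the 8-item Morisky medication adherence scale
#'
#' Items 1–7 are coded 0 (adherent) / 1 (non-adherent); item 8 is a 5-level
#' frequency (0–4) mapped to fractional non-adherence points (default
#' 0, 0.25, 0.5, 0.75, 1). The total counts non-adherence points in
#' \[0, 8\]; a *lower* score indicates better adherence.
#'
#' @param responses Vector of 8 items: first seven in \{0, 1\}, item 8 in
#'   0..4.
#' @param item8_map Numeric length-5 map for item 8's levels.
#' @return A one-row tibble with `higher_is_better = FALSE`.
#' @export
score_mmas8 <- function(responses,
                        item8_map = hf_config()$instruments$mmas8_item8_map) {
  if (length(responses) != 8) {
    abort(sprintf("MMAS-8 requires exactly 8 items (got %d)",
                  length(responses)))
  }
  check_items(responses[1:7], 7, 0, 1, "MMAS-8 (items 1-7)")
  check_items(responses[8], 1, 0, 4, "MMAS-8 (item 8)")
  total <- sum(responses[1:7]) + item8_map[responses[8] + 1]
  score_row("MMAS8", total, FALSE)
}

#' Score a Self-Care of Heart Failure Index subscale
#'
#' Raw item sums by default (the scale on which this program reports
#' subscale scores, e.g. a maintenance mean near 23); an optional 0–100
#' standardization is provided for interoperability with publications that
#' report standardized scores. Higher scores mean better self-care.
#'
#' @param subscale One of `"maintenance"`, `"management"`, `"confidence"`.
#' @param responses Item vector; counts and the common item range come from
#'   `config$instruments` (defaults: 10 / 6 / 6 items, each scored 1–4).
#' @param standardize If `TRUE`, rescale the raw sum to 0–100.
#' @param config An [hf_config()] list.
#' @return A one-row tibble with a `subscale` column.
#' @export
score_schfi <- function(subscale, responses, standardize = FALSE,
                        config = hf_config()) {
  ins <- config$instruments
  subscale <- match.arg(tolower(subscale), names(ins$schfi_items))
  n <- ins$schfi_items[[subscale]]
  rng <- ins$schfi_item_range
  check_items(responses, n, rng[1], rng[2],
              paste0("SCHFI ", subscale))
  total <- sum(responses)
  if (standardize) {
    total <- 100 * (total - n * rng[1]) / (n * (rng[2] - rng[1]))
  }
  score_row("SCHFI", total, TRUE, subscale = subscale,
            standardized = standardize)
}

#' Score the Kansas City Cardiomyopathy Questionnaire
#'
#' Twenty-three items in five domains (physical limitation, symptoms,
#' quality of life, social interference, self-efficacy). Each domain is the
#' mean of its answered items rescaled to 0–100, provided at least half the
#' domain's items are answered (`NA` allowed); a domain with more than half
#' its items missing is returned as `NA`. The overall summary averages the
#' four clinical domains (self-efficacy excluded, the conventional choice).
#' Lower scores mean worse symptoms and worse quality of life.
#'
#' @param responses Numeric vector of 23 items on the configured ordinal
#'   range (default 1–5); `NA` marks a skipped item.
#' @param config An [hf_config()] list (`$instruments$kccq_domains`,
#'   `$instruments$kccq_item_range`).
#' @return A one-row tibble with `total` (the summary), one column per
#'   domain, and `higher_is_better = TRUE`.
#' @export
score_kccq <- function(responses, config = hf_config()) {
  ins <- config$instruments
  domains <- ins$kccq_domains
  rng <- ins$kccq_item_range
  n_items <- max(unlist(domains))
  if (length(responses) != n_items) {
    abort(sprintf("KCCQ requires exactly %d items (got %d)",
                  n_items, length(responses)))
  }
  answered <- !is.na(responses)
  bad <- answered & (responses < rng[1] | responses > rng[2])
  if (any(bad)) {
    abort(sprintf("KCCQ item %d is out of range [%s, %s]",
                  which(bad)[1], rng[1], rng[2]))
  }
  domain_score <- function(idx) {
    vals <- responses[idx]
    if (mean(is.na(vals)) > 0.5) return(NA_real_)
    100 * (mean(vals, na.rm = TRUE) - rng[1]) / (rng[2] - rng[1])
  }
  scores <- purrr::map_dbl(domains, domain_score)
  clinical <- setdiff(names(domains), "self_efficacy")
  summary <- mean(scores[clinical], na.rm = TRUE)
  if (is.nan(summary)) summary <- NA_real_
  dplyr::bind_cols(
    score_row("KCCQ", summary, TRUE),
    tibble::as_tibble(as.list(scores))
  )
}

#' Score a long-format response table
#'
#' Tidy wrapper dispatching each respondent-by-instrument group of a
#' long-format item table to the matching scorer.
#'
#' @param responses A data frame with columns `respondent_id`,
#'   `instrument_id` (`PHQ9`, `AHFKT`, `MMAS8`, `FSSQ`, `CIRS`, `KCCQ`, or
#'   `SCHFI_MAINT`/`SCHFI_MGMT`/`SCHFI_CONF`), `item_index`, `value`.
#' @param config An [hf_config()] list.
#' @return A tibble of one scored row per respondent-instrument.
#' @export
score_responses <- function(responses, config = hf_config()) {
  required <- c("respondent_id", "instrument_id", "item_index", "value")
  missing_cols <- setdiff(required, names(responses))
  if (length(missing_cols) > 0) {
    abort(sprintf("responses are missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  one <- function(df) {
    v <- df$value[order(df$item_index)]
    id <- toupper(df$instrument_id[1])
    scored <- switch(id,
      PHQ9  = score_phq9(v),
      AHFKT = score_simple_sum("AHFKT", v),
      FSSQ  = score_simple_sum("FSSQ", v),
      CIRS  = score_simple_sum("CIRS", v),
      MMAS8 = score_mmas8(v, config$instruments$mmas8_item8_map),
      KCCQ  = score_kccq(v, config),
      SCHFI_MAINT = score_schfi("maintenance", v, config = config),
      SCHFI_MGMT  = score_schfi("management", v, config = config),
      SCHFI_CONF  = score_schfi("confidence", v, config = config),
      abort(sprintf("unknown instrument_id: %s", df$instrument_id[1]))
    )
    dplyr::bind_cols(tibble::tibble(respondent_id = df$respondent_id[1]),
                     scored)
  }
  responses |>
    dplyr::group_split(.data$respondent_id, .data$instrument_id) |>
    purrr::map(one) |>
    dplyr::bind_rows()
}

#' Screening eligibility gate
#'
#' Evaluates the trial's inclusion and exclusion criteria on a screening
#' profile. Inclusion: recent HF hospitalization, NYHA class II–III, age 30
#' or above, English, corrected near vision 20/50 or better (Snellen
#' denominator at most 50), a passed mid-frequency hearing screen (supplied
#' upstream as pass/fail), and willingness to use the app. Exclusion:
#' transplant status 1A or home inotropes, palliative/hospice enrollment,
#' stroke within the past year, aphasia or other major disability,
#' uncontrolled psychiatric disorder, MoCA total below 20, or dependent
#' living. *All* criteria are evaluated (no short-circuit) so the failure
#' list is complete for screening reports.
#'
#' @param profile A named list (or one-row data frame) with fields `age`,
#'   `nyha_class` (`"I"`–`"IV"`), `moca_total` (0–30),
#'   `visual_acuity_denominator` (x in 20/x), `hearing_pass`,
#'   `speaks_english`, `recent_hf_hospitalization`,
#'   `transplant_1a_or_inotrope`, `palliative_hospice`, `stroke_past_year`,
#'   `aphasia_major_disability`, `uncontrolled_psychiatric`,
#'   `dependent_living`, and optionally `willing_to_use_app` (default
#'   `TRUE`).
#' @return A list with `eligible` (logical) and `failed_criteria`
#'   (character vector of criterion ids; empty iff eligible).
#' @examples
#' p <- eligible_profile_template()
#' check_eligibility(p)$eligible
#' p$moca_total <- 19
#' check_eligibility(p)$failed_criteria
#' @export
check_eligibility <- function(profile) {
  profile <- as.list(profile)
  if (is.null(profile$willing_to_use_app)) profile$willing_to_use_app <- TRUE
  required <- c("age", "nyha_class", "moca_total",
                "visual_acuity_denominator", "hearing_pass",
                "speaks_english", "recent_hf_hospitalization",
                "transplant_1a_or_inotrope", "palliative_hospice",
                "stroke_past_year", "aphasia_major_disability",
                "uncontrolled_psychiatric", "dependent_living")
  missing_fields <- required[!purrr::map_lgl(required, function(f) {
    !is.null(profile[[f]]) && !is.na(profile[[f]])
  })]
  if (length(missing_fields) > 0) {
    abort(sprintf("profile is missing field(s): %s",
                  paste(missing_fields, collapse = ", ")))
  }
  if (profile$moca_total < 0 || profile$moca_total > 30) {
    abort("moca_total must lie in [0, 30]")
  }
  if (profile$visual_acuity_denominator <= 0) {
    abort("visual_acuity_denominator must be positive")
  }
  failed <- character()
  fail <- function(id, cond) if (cond) failed <<- c(failed, id)
  fail("recent_hf_hospitalization", !isTRUE(profile$recent_hf_hospitalization))
  fail("nyha_class", !profile$nyha_class %in% c("II", "III"))
  fail("age", profile$age < 30)
  fail("english", !isTRUE(profile$speaks_english))
  fail("vision", profile$visual_acuity_denominator > 50)
  fail("hearing", !isTRUE(profile$hearing_pass))
  fail("willing", !isTRUE(profile$willing_to_use_app))
  fail("transplant_1a_or_inotrope", isTRUE(profile$transplant_1a_or_inotrope))
  fail("palliative_hospice", isTRUE(profile$palliative_hospice))
  fail("stroke_past_year", isTRUE(profile$stroke_past_year))
  fail("aphasia_major_disability", isTRUE(profile$aphasia_major_disability))
  fail("uncontrolled_psychiatric", isTRUE(profile$uncontrolled_psychiatric))
  fail("moca", profile$moca_total < 20)
  fail("dependent_living", isTRUE(profile$dependent_living))
  list(eligible = length(failed) == 0, failed_criteria = failed)
}

#' @rdname check_eligibility
#' @export
eligible_profile_template <- function() {
  list(
    age = 53, nyha_class = "II", moca_total = 26,
    visual_acuity_denominator = 40, hearing_pass = TRUE,
    speaks_english = TRUE, recent_hf_hospitalization = TRUE,
    transplant_1a_or_inotrope = FALSE, palliative_hospice = FALSE,
    stroke_past_year = FALSE, aphasia_major_disability = FALSE,
    uncontrolled_psychiatric = FALSE, dependent_living = FALSE,
    willing_to_use_app = TRUE
  )
}
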