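#' @title Breathing-biofeedback and walking feedback scoring
#' @description
#' Paced deep breathing is scored against a 6 breaths/min target (controlled
#' breathing, versus spontaneous breathing near 15 breaths/min); walking is
#' scored against a personalized expected distance from a published
#' six-minute-walk (6MWD) reference regression on age, sex, height, and
#' weight. Scores are percentages in \[0, 100\].
#' @name exercise-feedback
NULL

#' Mean breathing rate of a session
#'
#' The session rate is 60 divided by the mean inter-breath interval in
#' seconds. A session with fewer than two breaths has no defined rate.
#'
#' @param breath_times Numeric vector of breath-completion times in seconds
#'   from session start, strictly increasing.
#' @return Breaths per minute, or `NA` when fewer than two breaths.
#' @examples
#' breathing_rate(seq(0, 60, by = 10))  # 6 breaths/min
#' @export
breathing_rate <- function(breath_times) {
  if (length(breath_times) < 2) return(NA_real_)
  iv <- diff(breath_times)
  if (any(iv <= 0)) abort("breath times must be strictly increasing")
  60 / mean(iv)
}

#' Score a breathing session against the paced target
#'
#' The score is the percentage of inter-breath intervals whose instantaneous
#' rate (60 / interval) lies within `target` plus or minus `tolerance`
#' breaths per minute.
#'
#' @param breath_times Breath-completion times in seconds (see
#'   [breathing_rate()]).
#' @param target Target rate in breaths/min (default 6).
#' @param tolerance Half-width of the in-target band in breaths/min
#'   (default 1).
#' @return A one-row tibble: `score_pct`, `rate_bpm` (session mean rate),
#'   `target`, `n_breaths`, `message`.
#' @examples
#' breathing_score(seq(0, 120, by = 10))$score_pct  # all intervals on target
#' @export
breathing_score <- function(breath_times, target = 6, tolerance = 1) {
  if (length(breath_times) < 2) {
    return(tibble::tibble(
      score_pct = 0, rate_bpm = NA_real_, target = target,
      n_breaths = length(breath_times),
      message = "session too short to score - try a longer session"
    ))
  }
  iv <- diff(breath_times)
  if (any(iv <= 0)) abort("breath times must be strictly increasing")
  inst <- 60 / iv
  in_band <- inst >= target - tolerance & inst <= target + tolerance
  pct <- 100 * mean(in_band)
  msg <- if (pct >= 80) {
    sprintf("great pacing - %0.0f%% of breaths at the %g/min target", pct,
            target)
  } else {
    sprintf("keep practicing toward %g breaths per minute", target)
  }
  tibble::tibble(score_pct = pct, rate_bpm = breathing_rate(breath_times),
                 target = target, n_breaths = length(breath_times),
                 message = msg)
}

#' Reference-equation registry for expected walk distance
#'
#' Published healthy-adult six-minute-walk-distance regressions, keyed by
#' id. The default, `"enright_sherrill"`, predicts 6MWD in meters from
#' height (cm), weight (kg), and age (years) with sex-specific
#' coefficients. This is a population reference equation, not the mobile
#' program's own (unpublished) formula; alternative equations can be
#' registered by supplying the same coefficient structure.
#'
#' @return A named list of equations; each has per-sex coefficient vectors
#'   `(intercept, height_cm, weight_kg, age)`.
#' @export
walk_equations <- function() {
  list(
    enright_sherrill = list(
      male   = c(intercept = -309, height_cm = 7.57, weight_kg = -1.76,
                 age = -5.02),
      female = c(intercept = 667,  height_cm = 2.11, weight_kg = -2.29,
                 age = -5.78)
    )
  )
}

#' Expected six-minute-walk distance for a person
#'
#' Deterministic expected distance (meters) from the configured reference
#' equation, floored at 0.
#'
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param height_cm Height in centimeters.
#' @param weight_kg Weight in kilograms.
#' @param equation Equation id in the registry (default
#'   `"enright_sherrill"`).
#' @param registry Equation registry, see [walk_equations()].
#' @return Expected distance in meters (vectorized over profiles).
#' @examples
#' expected_walk_distance(60, "female", 165, 70)
#' @export
expected_walk_distance <- function(age, sex, height_cm, weight_kg,
                                   equation = "enright_sherrill",
                                   registry = walk_equations()) {
  if (!equation %in% names(registry)) {
    abort(sprintf("unknown reference equation: %s", equation))
  }
  sex <- tolower(as.character(sex))
  if (any(!sex %in% c("female", "male"))) {
    abort("sex must be 'female' or 'male'")
  }
  if (any(age <= 0) || any(height_cm <= 0) || any(weight_kg <= 0)) {
    abort("age, height_cm, and weight_kg must all be positive")
  }
  eq <- registry[[equation]]
  dist <- purrr::map_dbl(seq_along(age), function(i) {
    b <- eq[[sex[pmin(i, length(sex))]]]
    b[["intercept"]] + b[["height_cm"]] * height_cm[pmin(i, length(height_cm))] +
      b[["weight_kg"]] * weight_kg[pmin(i, length(weight_kg))] +
      b[["age"]] * age[pmin(i, length(age))]
  })
  pmax(0, dist)
}

#' Score a walking session against the personalized expectation
#'
#' The score is the walked distance as a percentage of the expected
#' distance, capped at 100 (over-achievement is neither penalized nor
#' rewarded). The feedback message encourages the program's 3–4 walking
#' sessions per week.
#'
#' @param distance_m Distance walked in meters (>= 0).
#' @param age,sex,height_cm,weight_kg Person profile, see
#'   [expected_walk_distance()].
#' @param equation,registry Reference equation selection.
#' @return A one-row tibble: `score_pct`, `distance_m`, `expected_m`,
#'   `message`.
#' @export
walking_score <- function(distance_m, age, sex, height_cm, weight_kg,
                          equation = "enright_sherrill",
                          registry = walk_equations()) {
  if (distance_m < 0) abort("distance_m must be non-negative")
  expected <- expected_walk_distance(age, sex, height_cm, weight_kg,
                                     equation, registry)
  if (expected == 0) {
    abort("expected distance is zero for this profile; cannot score")
  }
  pct <- max(0, min(100, 100 * distance_m / expected))
  tibble::tibble(
    score_pct = pct, distance_m = distance_m, expected_m = expected,
    message = sprintf(
      "you walked %0.0f%% of your expected distance - aim for 3 to 4 walks a week",
      pct)
  )
}
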