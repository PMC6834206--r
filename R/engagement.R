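#' @title Engagement analytics over feature-access logs
#' @description
#' Engagement is the percentage of protocol days on which the patient
#' accessed any app feature at least once: 100 x (distinct active days) /
#' (window length). The denominator is always the protocol window (30 days
#' by default), not days-until-last-use, so 24 active days of a 30-day
#' window is 80% engagement. Day attribution uses the patient-local date
#' carried in each timestamp's own zone offset.
#' @name engagement-analytics
NULL

FEATURES <- c("MED_TRACKER", "ASSESSMENT", "BREATHING", "WALKING",
              "STATS", "VITALS", "CHF_INFO")

# Patient-local calendar date of an ISO-8601 timestamp: the date literal at
# the head of the string already is the local date (the offset, if any,
# applies to the clock time as written). POSIXct input uses its own tzone.
local_date <- function(timestamp) {
  if (inherits(timestamp, "POSIXct")) {
    return(as.Date(timestamp, tz = attr(timestamp, "tzone") %||% "UTC"))
  }
  ts <- as.character(timestamp)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}", ts)
  if (!all(ok)) {
    abort(sprintf("unparseable timestamp: %s", ts[which(!ok)[1]]))
  }
  as.Date(substr(ts, 1, 10))
}

#' Summarize one patient's engagement over a study window
#'
#' @param events A data frame of one patient's access events with columns
#'   `patient_id`, `timestamp` (ISO-8601 string or `POSIXct`), `feature`
#'   (one of MED_TRACKER, ASSESSMENT, BREATHING, WALKING, STATS, VITALS,
#'   CHF_INFO). Zero rows allowed.
#' @param window_start First day of the protocol window (`Date`).
#' @param window_days Window length in whole days (default 30); the window
#'   is the half-open interval `[window_start, window_start + window_days)`.
#' @param low_threshold_pct Active-day percentage below which the
#'   low-engagement flag is raised (default 50).
#' @return A one-row tibble: `patient_id`, `active_days`, `window_days`,
#'   `engagement_pct`, `daily_assessment_completion_pct`,
#'   `per_feature_days` (list column, named counts), `excluded_events`
#'   (events outside the window), `low_engagement_flag`.
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = "p1",
#'   timestamp = paste0("2024-03-", sprintf("%02d", 1:24), "T09:00:00-05:00"),
#'   feature = "ASSESSMENT"
#' )
#' engagement_summary(ev, as.Date("2024-03-01"))$engagement_pct
#' @export
engagement_summary <- function(events, window_start, window_days = 30,
                               low_threshold_pct = 50) {
  if (window_days < 1) abort("window_days must be at least 1")
  window_start <- as.Date(window_start)
  ids <- unique(events$patient_id)
  if (length(ids) > 1) {
    abort(sprintf("events mix %d patients; summarize one patient at a time",
                  length(ids)))
  }
  pid <- if (length(ids) == 1) ids else NA_character_
  if (nrow(events) > 0) {
    bad <- !events$feature %in% FEATURES
    if (any(bad)) {
      abort(sprintf("unknown feature: %s", events$feature[which(bad)[1]]))
    }
  }
  dates <- if (nrow(events) > 0) local_date(events$timestamp) else as.Date(character())
  in_window <- dates >= window_start & dates < window_start + window_days
  active <- unique(dates[in_window])
  per_feature <- if (nrow(events) > 0) {
    tapply(dates[in_window], events$feature[in_window],
           function(d) length(unique(d)))
  } else NULL
  per_feature <- as.list(per_feature)
  assess_days <- length(unique(
    dates[in_window & events$feature == "ASSESSMENT"]
  ))
  pct <- 100 * length(active) / window_days
  tibble::tibble(
    patient_id = pid,
    active_days = length(active),
    window_days = window_days,
    engagement_pct = pct,
    daily_assessment_completion_pct = 100 * assess_days / window_days,
    per_feature_days = list(per_feature),
    excluded_events = sum(!in_window),
    low_engagement_flag = pct < low_threshold_pct
  )
}

#' Per-patient engagement summaries for a multi-patient log
#'
#' @param events A multi-patient access-event table (see
#'   [engagement_summary()]).
#' @inheritParams engagement_summary
#' @return A tibble with one summary row per patient.
#' @export
engagement_by_patient <- function(events, window_start, window_days = 30,
                                  low_threshold_pct = 50) {
  events |>
    dplyr::group_split(.data$patient_id) |>
    purrr::map(engagement_summary, window_start = window_start,
               window_days = window_days,
               low_threshold_pct = low_threshold_pct) |>
    dplyr::bind_rows()
}

#' Cohort mean engagement
#'
#' Unweighted arithmetic mean of per-patient engagement percentages.
#'
#' @param summaries A tibble of [engagement_summary()] rows (nonempty).
#' @return A single percentage.
#' @export
cohort_engagement <- function(summaries) {
  if (nrow(summaries) == 0) abort("no engagement summaries supplied")
  mean(summaries$engagement_pct)
}

#' Performance-tracker trend series
#'
#' Extracts an ordered per-day series of one tracked metric for display in
#' the performance tracker. One point per day with data, chronologically
#' sorted; duplicate same-day values collapse last-write-wins (matching the
#' triage day boundary); gaps are preserved, never interpolated.
#'
#' @param data A data frame carrying the metric: assessments (for `weight`,
#'   `sbp`, `dbp`, `hr`, `symptoms`) with a `date` column, or walk records
#'   (for `distance`) with `date` and `distance_m`.
#' @param metric One of `"weight"`, `"sbp"`, `"dbp"`, `"hr"`,
#'   `"symptoms"`, `"distance"`.
#' @return A tibble with columns `date` and `value` (for `symptoms`, the
#'   ordinal severity level as an ordered factor).
#' @export
trend_series <- function(data, metric) {
  col <- switch(metric,
    weight = "weight_lb", sbp = "sbp", dbp = "dbp", hr = "hr",
    symptoms = "symptom_severity", distance = "distance_m",
    abort(sprintf("unknown metric: %s", metric))
  )
  if (!col %in% names(data)) {
    abort(sprintf("metric '%s' needs column '%s' in the input", metric, col))
  }
  out <- tibble::tibble(date = as.Date(data$date), value = data[[col]]) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$date) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$date)
  if (metric == "symptoms") out$value <- as_severity(out$value)
  out
}
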