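#' @title Zone-based triage for daily heart-failure assessments
#' @description
#' The triage engine classifies each patient-day into one of four escalating
#' self-care zones from the day's symptom severity and recent weight gain:
#'
#' * **green** — stable symptoms, no weight-gain rule fired: continue current
#'   self-care practices.
#' * **yellow** — mild (or worse) symptoms, or a gain of at least 3 lb in one
#'   day or 5 lb in a week: self-action (extra diuretic dose if prescribed)
#'   and a call to home care.
#' * **orange** — moderate symptoms together with a gain of more than 5 lb:
#'   call the provider now; the care coordinator is notified.
#' * **red** — symptoms requiring immediate attention: emergency escalation
#'   with a panic alert to the coordinator and home care staff.
#'
#' Rules are evaluated most-severe-first and the most severe rule that fires
#' decides the zone; every fired rule is reported. All actions are dry-run
#' records — the package never dials, notifies, or messages anything.
#' @name triage-engine
NULL

ZONE_LEVELS <- c("green", "yellow", "orange", "red")
SEVERITY_LEVELS <- c("stable", "mild", "moderate", "immediate")

as_severity <- function(x) {
  x <- tolower(as.character(x))
  bad <- !x %in% SEVERITY_LEVELS
  if (any(bad)) {
    abort(sprintf("invalid symptom severity: %s (must be one of %s)",
                  paste(unique(x[bad]), collapse = ", "),
                  paste(SEVERITY_LEVELS, collapse = "/")))
  }
  factor(x, levels = SEVERITY_LEVELS, ordered = TRUE)
}

#' Weight-gain deltas for a day's assessment
#'
#' Computes the one-day and trailing-week weight gains used by the zone
#' rules. The one-day delta compares today's weight with the most recent
#' prior weight; if that weight is older than one day it is carried forward
#' up to `staleness_days` (beyond which the delta is `NA` and flagged stale).
#' The weekly delta compares today's weight with the *minimum* weight
#' observed in the half-open trailing window `(today - 7 days, today)` — the
#' most sensitive reference for a gain "over the week".
#'
#' @param history A data frame of prior assessments with columns `date`
#'   (`Date`) and `weight_lb`, all strictly before `date`. May have zero rows.
#' @param weight_lb Today's weight in pounds (> 0).
#' @param date Today's calendar date (`Date`).
#' @param staleness_days Carry-forward limit, in days, for the one-day
#'   reference (default 3).
#' @return A one-row tibble: `delta_1d`, `delta_7d`, `ref_date_1d`,
#'   `ref_date_7d`, `stale`. Deltas are `NA` when no usable reference exists.
#' @examples
#' h <- tibble::tibble(date = as.Date("2024-03-01"), weight_lb = 180)
#' weight_deltas(h, weight_lb = 183, date = as.Date("2024-03-02"))
#' @export
weight_deltas <- function(history, weight_lb, date, staleness_days = 3) {
  if (!is.numeric(weight_lb) || length(weight_lb) != 1 || is.na(weight_lb) ||
      weight_lb <= 0) {
    abort(sprintf("today's weight must be a single positive number (got %s)",
                  deparse(weight_lb)))
  }
  date <- as.Date(date)
  empty <- is.null(history) || nrow(history) == 0
  if (!empty) {
    if (any(history$weight_lb <= 0, na.rm = TRUE)) {
      bad <- which(history$weight_lb <= 0)[1]
      abort(sprintf("non-positive weight in history on %s",
                    format(history$date[bad])))
    }
    if (any(history$date >= date)) {
      abort("history dates must all precede today's date")
    }
    history <- dplyr::arrange(history, .data$date)
  }

  delta_1d <- NA_real_
  ref_1d <- as.Date(NA)
  stale <- FALSE
  if (!empty) {
    last <- dplyr::slice_tail(history, n = 1)
    gap <- as.integer(date - last$date)
    if (gap - 1 <= staleness_days) {
      # gap == 1: true yesterday; otherwise the last observation is carried
      # forward to stand in for yesterday, up to the staleness limit
      delta_1d <- weight_lb - last$weight_lb
      ref_1d <- last$date
    } else {
      stale <- TRUE
    }
  }

  delta_7d <- NA_real_
  ref_7d <- as.Date(NA)
  if (!empty) {
    in_window <- history$date > (date - 7) & history$date < date
    if (any(in_window)) {
      w <- history$weight_lb[in_window]
      d <- history$date[in_window]
      i <- which.min(w)
      delta_7d <- weight_lb - w[i]
      ref_7d <- d[i]
    } else {
      stale <- TRUE
    }
  }

  tibble::tibble(delta_1d = delta_1d, delta_7d = delta_7d,
                 ref_date_1d = ref_1d, ref_date_7d = ref_7d, stale = stale)
}

#' Classify a patient-day into a triage zone
#'
#' Evaluates the zone rules on the weight deltas and reported symptom
#' severity. `NA` deltas contribute no evidence: weight rules simply do not
#' fire, and symptoms alone can still escalate. The zone is the most severe
#' among all fired rules, so it is monotone non-decreasing in symptom
#' severity at fixed deltas and in each delta at fixed severity.
#'
#' @param delta_1d,delta_7d Weight gains in pounds (may be `NA`).
#' @param symptom_severity One of `"stable"`, `"mild"`, `"moderate"`,
#'   `"immediate"`.
#' @param config An [hf_config()] list (thresholds under `$triage`).
#' @return A one-row tibble: `zone` (ordered factor green < yellow < orange
#'   < red) and `triggered_rules` (list column of fired rule ids, most severe
#'   first).
#' @examples
#' classify_zone(0, 0, "stable")$zone
#' classify_zone(NA, 6, "moderate")$zone
#' @export
classify_zone <- function(delta_1d, delta_7d, symptom_severity,
                          config = hf_config()) {
  sev <- as_severity(symptom_severity)
  if (length(sev) != 1) abort("classify_zone() handles one assessment at a time")
  tri <- config$triage
  d1 <- if (is.null(delta_1d) || is.na(delta_1d)) -Inf else delta_1d
  d7 <- if (is.null(delta_7d) || is.na(delta_7d)) -Inf else delta_7d
  gain <- max(d1, d7)

  rules <- c(
    red_immediate_symptoms   = sev == "immediate",
    orange_moderate_gain_gt5 = sev == "moderate" && gain > tri$orange_gain_lb,
    yellow_symptoms          = sev >= "mild" && sev < "immediate",
    yellow_gain_1d           = d1 >= tri$gain_1d_lb,
    yellow_gain_7d           = d7 >= tri$gain_7d_lb
  )
  zone_of_rule <- c(
    red_immediate_symptoms = "red", orange_moderate_gain_gt5 = "orange",
    yellow_symptoms = "yellow", yellow_gain_1d = "yellow",
    yellow_gain_7d = "yellow"
  )
  fired <- names(rules)[rules]
  zone <- if (length(fired) == 0) "green" else {
    ZONE_LEVELS[max(match(zone_of_rule[fired], ZONE_LEVELS))]
  }
  # new_tibble keeps this hot path cheap (triage calls it once per day)
  tibble::new_tibble(
    list(zone = factor(zone, levels = ZONE_LEVELS, ordered = TRUE),
         triggered_rules = list(fired)),
    nrow = 1L
  )
}

#' Feedback action for a triage zone
#'
#' Maps a zone to its feedback message, action kind, and notification
#' targets. The yellow message includes the extra-diuretic clause only when a
#' PRN "water pill" is prescribed; the call-home-care clause is always
#' present. Red produces an emergency record with a 911 placeholder and panic
#' alert targets. Every action is inert (`dry_run = TRUE`): this function
#' records what the app would do, it performs nothing.
#'
#' @param zone A zone label (`"green"`, `"yellow"`, `"orange"`, `"red"`).
#' @param diuretic_prescribed Logical; does the patient have a PRN diuretic?
#' @return A one-row tibble: `zone`, `kind` (`CONTINUE`, `SELF_ACTION`,
#'   `CALL_PROVIDER`, `EMERGENCY`), `message`, `notify_targets` (list
#'   column), `dry_run` (always `TRUE`).
#' @examples
#' zone_action("yellow", diuretic_prescribed = FALSE)$message
#' @export
zone_action <- function(zone, diuretic_prescribed = FALSE) {
  zone <- match.arg(tolower(as.character(zone)), ZONE_LEVELS)
  call_clause <- paste("call the home care staff if receiving home care",
                       "or your doctor's office")
  out <- switch(zone,
    green = list(
      kind = "CONTINUE",
      message = "stable with no change-continue current self-care practices",
      targets = character()
    ),
    yellow = list(
      kind = "SELF_ACTION",
      message = if (isTRUE(diuretic_prescribed)) {
        paste("take an extra dose of water pill if prescribed by your doctor",
              "and", call_clause)
      } else {
        call_clause
      },
      targets = "home_care"
    ),
    orange = list(
      kind = "CALL_PROVIDER",
      message = "call home care staff or the doctor's office now",
      targets = c("coordinator", "home_care")
    ),
    red = list(
      kind = "EMERGENCY",
      message = paste("emergency: 911 would be dialed (placeholder) and a",
                      "panic alert sent to the study coordinator and home",
                      "care staff"),
      targets = c("emergency", "coordinator", "home_care")
    )
  )
  tibble::tibble(
    zone = factor(zone, levels = ZONE_LEVELS, ordered = TRUE),
    kind = out$kind, message = out$message,
    notify_targets = list(out$targets), dry_run = TRUE
  )
}

#' NYHA severity index from symptom responses
#'
#' Classifies a patient into NYHA functional class I–IV from a named logical
#' response vector via a configurable rule table. The default table is the
#' standard activity-limitation ladder: symptoms at rest imply class IV;
#' symptoms with less-than-ordinary activity, class III; with ordinary
#' activity, class II; otherwise class I. The mapping is pure: identical
#' responses always yield the same class.
#'
#' @param responses Named list or logical vector with the fields required by
#'   the rule table (for the default: `symptoms_at_rest`,
#'   `symptoms_less_than_ordinary_activity`, `symptoms_ordinary_activity`).
#' @param rule_table A data frame with columns `class` and `requires`,
#'   evaluated top to bottom; the first row whose `requires` field is `TRUE`
#'   wins, and an `NA` requirement is the fallback class.
#' @return A one-row tibble: `nyha_class` (factor I < II < III < IV) and
#'   `rule_table_id`.
#' @examples
#' severity_index(list(symptoms_at_rest = TRUE,
#'                     symptoms_less_than_ordinary_activity = TRUE,
#'                     symptoms_ordinary_activity = TRUE))
#' @export
severity_index <- function(responses, rule_table = nyha_rule_table()) {
  responses <- as.list(responses)
  needed <- rule_table$requires[!is.na(rule_table$requires)]
  missing_fields <- setdiff(needed, names(responses))
  if (length(missing_fields) > 0) {
    abort(sprintf("responses are missing required field(s): %s",
                  paste(missing_fields, collapse = ", ")))
  }
  cls <- NA_character_
  for (i in seq_len(nrow(rule_table))) {
    req <- rule_table$requires[i]
    if (is.na(req) || isTRUE(responses[[req]])) {
      cls <- rule_table$class[i]
      break
    }
  }
  tibble::tibble(
    nyha_class = factor(cls, levels = c("I", "II", "III", "IV"),
                        ordered = TRUE),
    rule_table_id = attr(rule_table, "id") %||% "custom"
  )
}

#' @rdname severity_index
#' @export
nyha_rule_table <- function() {
  structure(
    tibble::tibble(
      class = c("IV", "III", "II", "I"),
      requires = c("symptoms_at_rest",
                   "symptoms_less_than_ordinary_activity",
                   "symptoms_ordinary_activity",
                   NA_character_)
    ),
    id = "nyha_default"
  )
}

#' Map per-item symptom answers to an overall severity level
#'
#' When the app collects a vector of symptom items rather than a single
#' 4-level severity, the overall level is the maximum item level
#' (fail-safe: one alarming answer escalates the day).
#'
#' @param item_levels Character vector of per-item levels
#'   (`stable`/`mild`/`moderate`/`immediate`) or integer codes 0–3.
#' @return A single severity string.
#' @export
symptom_severity_from_items <- function(item_levels) {
  if (length(item_levels) == 0) abort("at least one symptom item is required")
  if (is.numeric(item_levels)) {
    if (any(!item_levels %in% 0:3)) {
      abort("numeric symptom items must be coded 0 (stable) to 3 (immediate)")
    }
    item_levels <- SEVERITY_LEVELS[item_levels + 1]
  }
  sev <- as_severity(item_levels)
  as.character(max(sev))
}

#' Upcoming medication reminder firings
#'
#' Enumerates all active reminder firings in the half-open interval
#' `(now, now + horizon_hours]`, chronologically sorted. Inactive schedules
#' contribute nothing.
#'
#' @param schedules A data frame with columns `medication` (character),
#'   `time` (local clock time `"HH:MM"`), and `active` (logical). A
#'   medication with several daily doses has one row per time.
#' @param now A `POSIXct` local datetime.
#' @param horizon_hours Look-ahead horizon in hours (> 0).
#' @return A tibble with columns `fires_at` (`POSIXct`) and `medication`.
#' @examples
#' sched <- tibble::tibble(medication = "furosemide", time = "08:00",
#'                         active = TRUE)
#' next_reminders(sched, as.POSIXct("2024-03-01 07:00:00", tz = "UTC"), 2)
#' @export
next_reminders <- function(schedules, now, horizon_hours) {
  if (!is.numeric(horizon_hours) || horizon_hours <= 0) {
    abort("horizon_hours must be positive")
  }
  now <- as.POSIXct(now)
  tz <- attr(now, "tzone") %||% ""
  end <- now + horizon_hours * 3600
  active <- dplyr::filter(schedules, .data$active)
  if (nrow(active) == 0) {
    return(tibble::tibble(fires_at = now[0], medication = character()))
  }
  days <- seq(as.Date(now, tz = tz), as.Date(end, tz = tz) + 1, by = "day")
  grid <- tidyr::expand_grid(day = days,
                             active[, c("medication", "time")])
  grid$fires_at <- as.POSIXct(paste(grid$day, grid$time), tz = tz)
  grid <- grid[grid$fires_at > now & grid$fires_at <= end, ]
  dplyr::arrange(
    tibble::tibble(fires_at = grid$fires_at, medication = grid$medication),
    .data$fires_at, .data$medication
  )
}

#' Run triage over an assessment table
#'
#' Applies [weight_deltas()], [classify_zone()], and [zone_action()] to each
#' patient-day of an assessment table, in chronological order per patient.
#' Duplicate same-day entries collapse last-write-wins before triage.
#'
#' @param assessments A data frame with columns `patient_id`, `date`
#'   (`Date` or ISO-8601 string), `weight_lb` (pounds; alternatively a
#'   `weight_kg` column, converted at 2.20462 lb/kg), `symptom_severity`,
#'   and optionally `diuretic_prescribed` (defaults to `FALSE`), `sbp`,
#'   `dbp`, `hr`.
#' @param config An [hf_config()] list.
#' @return A tibble with one row per patient-day: the echoed inputs, the
#'   computed deltas and staleness flag, `zone`, `triggered_rules` (list
#'   column), and the action fields `action_kind`, `message`,
#'   `notify_targets` (list column), `dry_run`.
#' @examples
#' a <- tibble::tibble(
#'   patient_id = "p1",
#'   date = as.Date("2024-03-01") + 0:1,
#'   weight_lb = c(180, 183.5),
#'   symptom_severity = c("stable", "stable")
#' )
#' triage(a)[, c("date", "delta_1d", "zone", "action_kind")]
#' @export
triage <- function(assessments, config = hf_config()) {
  a <- validate_assessments(assessments)
  a <- a |>
    dplyr::group_by(.data$patient_id, .data$date) |>
    dplyr::slice_tail(n = 1) |>   # last-write-wins within a day
    dplyr::ungroup() |>
    dplyr::arrange(.data$patient_id, .data$date)

  per_patient <- function(df) {
    out <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      hist <- df[seq_len(i - 1), c("date", "weight_lb")]
      d <- weight_deltas(hist, df$weight_lb[i], df$date[i],
                         staleness_days = config$triage$staleness_days)
      z <- classify_zone(d$delta_1d, d$delta_7d, df$symptom_severity[i],
                         config = config)
      act <- zone_action(as.character(z$zone), df$diuretic_prescribed[i])
      out[[i]] <- tibble::tibble(
        patient_id = df$patient_id[i], date = df$date[i],
        weight_lb = df$weight_lb[i],
        symptom_severity = df$symptom_severity[i],
        delta_1d = d$delta_1d, delta_7d = d$delta_7d, stale = d$stale,
        zone = z$zone, triggered_rules = z$triggered_rules,
        action_kind = act$kind, message = act$message,
        notify_targets = act$notify_targets, dry_run = act$dry_run
      )
    }
    dplyr::bind_rows(out)
  }

  a |>
    dplyr::group_split(.data$patient_id) |>
    purrr::map(per_patient) |>
    dplyr::bind_rows()
}

validate_assessments <- function(assessments) {
  a <- tibble::as_tibble(assessments)
  if (!"weight_lb" %in% names(a) && "weight_kg" %in% names(a)) {
    a$weight_lb <- a$weight_kg * LB_PER_KG
  }
  required <- c("patient_id", "date", "weight_lb", "symptom_severity")
  missing_cols <- setdiff(required, names(a))
  if (length(missing_cols) > 0) {
    abort(sprintf("assessments are missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  a$date <- as.Date(a$date)
  if (any(is.na(a$date))) abort("assessments contain unparseable dates")
  bad <- which(!is.finite(a$weight_lb) | a$weight_lb <= 0)
  if (length(bad) > 0) {
    abort(sprintf("non-positive or missing weight for patient %s on %s (row %d)",
                  a$patient_id[bad[1]], format(a$date[bad[1]]), bad[1]))
  }
  as_severity(a$symptom_severity)  # validates levels
  a$symptom_severity <- tolower(as.character(a$symptom_severity))
  if (!"diuretic_prescribed" %in% names(a)) a$diuretic_prescribed <- FALSE
  a$diuretic_prescribed <- as.logical(a$diuretic_prescribed)
  a
}
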