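#' @title Shared I/O and the end-to-end pipeline
#' @description
#' CSV readers with schema validation and located errors, JSON/JSONL
#' writers, and [run_pipeline()], which wires triage, engagement,
#' instrument scoring, and the outcome report together. Dates are ISO-8601;
#' weights are canonically pounds, with a `weight_kg` column accepted and
#' converted (2.20462 lb/kg) on read. All writes go through a temp file and
#' an atomic rename.
#' @name pipeline-io
NULL

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s file %s is missing column(s): %s", what, path,
                  paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Read an assessments CSV
#'
#' Expected columns: `patient_id`, `date` (ISO-8601), `weight_lb` (or
#' `weight_kg`), `symptom_severity` (stable/mild/moderate/immediate), and
#' optionally `sbp`, `dbp`, `hr`, `diuretic_prescribed` (0/1). Rows
#' violating the schema are rejected with their row number.
#'
#' @param path CSV path.
#' @return A validated assessments tibble.
#' @export
read_assessments <- function(path) {
  df <- read_checked_csv(path, c("patient_id", "date"), "assessments")
  validate_assessments(df)
}

#' Read a feature-access event CSV
#'
#' Expected columns: `patient_id`, `timestamp` (ISO-8601 with zone offset),
#' `feature`.
#'
#' @param path CSV path.
#' @return An events tibble.
#' @export
read_events <- function(path) {
  df <- read_checked_csv(path, c("patient_id", "timestamp", "feature"),
                         "events")
  bad <- which(!df$feature %in% FEATURES)
  if (length(bad) > 0) {
    abort(sprintf("events file row %d has unknown feature '%s'",
                  bad[1], df$feature[bad[1]]))
  }
  local_date(df$timestamp)  # validates parseability
  tibble::as_tibble(df)
}

#' Read a two-arm outcome CSV
#'
#' Expected columns: `patient_id`, `group`, `outcome_id`, `baseline`,
#' `followup` (blank follow-up marks a non-completer).
#'
#' @param path CSV path.
#' @return An outcomes tibble.
#' @export
read_outcomes <- function(path) {
  df <- read_checked_csv(
    path, c("patient_id", "group", "outcome_id", "baseline", "followup"),
    "outcomes")
  bad <- which(is.na(df$baseline))
  if (length(bad) > 0) {
    abort(sprintf("outcomes file row %d has a missing baseline", bad[1]))
  }
  tibble::as_tibble(df)
}

#' Read a long-format instrument response CSV
#'
#' Expected columns: `respondent_id`, `instrument_id`, `item_index`,
#' `value`.
#'
#' @param path CSV path.
#' @return A responses tibble.
#' @export
read_responses <- function(path) {
  read_checked_csv(
    path, c("respondent_id", "instrument_id", "item_index", "value"),
    "responses")
}

write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp, useBytes = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write triage results as JSON lines
#'
#' One JSON object per patient-day with the zone, fired rules, and action
#' record.
#'
#' @param results A [triage()] result tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_triage_jsonl <- function(results, path) {
  lines <- purrr::map_chr(seq_len(nrow(results)), function(i) {
    jsonlite::toJSON(list(
      patient_id = results$patient_id[i],
      date = format(results$date[i]),
      weight_lb = results$weight_lb[i],
      delta_1d = results$delta_1d[i],
      delta_7d = results$delta_7d[i],
      zone = as.character(results$zone[i]),
      triggered_rules = results$triggered_rules[[i]],
      action = list(kind = results$action_kind[i],
                    message = results$message[i],
                    notify_targets = results$notify_targets[[i]],
                    dry_run = results$dry_run[i])
    ), auto_unbox = TRUE, na = "null", digits = NA)
  })
  write_atomic(lines, path)
}

#' Run the end-to-end pipeline
#'
#' Triage over the assessment table, engagement summaries over the event
#' log, optional instrument scoring, and the two-arm outcome report, all
#' written to `out_dir` (`triage.jsonl`, `engagement.json`, `scores.json`,
#' `report.csv`, `report.json`). Each red or orange patient-day is logged
#' as an escalation message. Identical inputs and configuration always
#' produce byte-identical output files.
#'
#' @param assessments Assessments table or CSV path.
#' @param events Events table or CSV path (optional).
#' @param outcomes Outcomes table or CSV path (optional).
#' @param responses Instrument response table or CSV path (optional).
#' @param out_dir Output directory (created if needed).
#' @param config An [hf_config()] list.
#' @param window_start First engagement-window day; defaults to the
#'   earliest assessment date.
#' @return Invisibly, a list of the computed tibbles (`triage`,
#'   `engagement`, `scores`, `report`) and output paths.
#' @export
run_pipeline <- function(assessments, events = NULL, outcomes = NULL,
                         responses = NULL, out_dir = ".",
                         config = hf_config(), window_start = NULL) {
  if (is.character(assessments)) assessments <- read_assessments(assessments)
  if (is.character(events)) events <- read_events(events)
  if (is.character(outcomes)) outcomes <- read_outcomes(outcomes)
  if (is.character(responses)) responses <- read_responses(responses)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  tri <- triage(assessments, config = config)
  esc <- tri[tri$zone >= "orange", ]
  for (i in seq_len(nrow(esc))) {
    message(sprintf("escalation: patient %s on %s -> %s (%s)",
                    esc$patient_id[i], format(esc$date[i]),
                    toupper(as.character(esc$zone[i])), esc$action_kind[i]))
  }
  paths$triage <- file.path(out_dir, "triage.jsonl")
  write_triage_jsonl(tri, paths$triage)

  eng <- NULL
  if (!is.null(events)) {
    ws <- window_start %||% min(as.Date(assessments$date))
    eng <- engagement_by_patient(
      events, window_start = ws,
      window_days = config$engagement$window_days,
      low_threshold_pct = config$engagement$low_engagement_pct)
    eng_json <- jsonlite::toJSON(list(
      window_start = format(as.Date(ws)),
      window_days = config$engagement$window_days,
      cohort_mean_engagement_pct = cohort_engagement(eng),
      patients = purrr::map(seq_len(nrow(eng)), function(i) list(
        patient_id = eng$patient_id[i],
        active_days = eng$active_days[i],
        engagement_pct = eng$engagement_pct[i],
        daily_assessment_completion_pct =
          eng$daily_assessment_completion_pct[i],
        per_feature_days = eng$per_feature_days[[i]],
        low_engagement_flag = eng$low_engagement_flag[i]
      ))
    ), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths$engagement <- file.path(out_dir, "engagement.json")
    write_atomic(eng_json, paths$engagement)
  }

  scores <- NULL
  if (!is.null(responses)) {
    scores <- score_responses(responses, config = config)
    score_json <- jsonlite::toJSON(
      purrr::map(seq_len(nrow(scores)), function(i) {
        row <- as.list(scores[i, setdiff(names(scores), character(0))])
        purrr::map(row, function(v) if (is.list(v)) v[[1]] else v)
      }),
      auto_unbox = TRUE, pretty = TRUE, na = "null", digits = NA)
    paths$scores <- file.path(out_dir, "scores.json")
    write_atomic(score_json, paths$scores)
  }

  report <- NULL
  if (!is.null(outcomes)) {
    report <- outcome_report(outcomes)
    paths$report_csv <- file.path(out_dir, "report.csv")
    tmp <- paste0(paths$report_csv, ".tmp")
    readr::write_csv(tibble::as_tibble(report), tmp)
    file.rename(tmp, paths$report_csv)
    rep_json <- jsonlite::toJSON(tibble::as_tibble(report),
                                 dataframe = "rows", na = "null",
                                 pretty = TRUE, digits = NA)
    paths$report_json <- file.path(out_dir, "report.json")
    write_atomic(rep_json, paths$report_json)
  }

  invisible(list(triage = tri, engagement = eng, scores = scores,
                 report = report, paths = paths))
}
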