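# Shared builders for test fixtures (all generated in code).

make_history <- function(dates, weights, patient_id = "p1") {
  tibble::tibble(date = as.Date(dates), weight_lb = weights)
}

make_assessments <- function(dates, weights, severity = "stable",
                             patient_id = "p1", diuretic = FALSE) {
  tibble::tibble(
    patient_id = patient_id, date = as.Date(dates), weight_lb = weights,
    symptom_severity = severity, diuretic_prescribed = diuretic
  )
}

# Complete (no-dropout) two-arm outcome table in which every completer sits
# exactly at the configured group mean, so change scores are exact arithmetic
# on the configured means.
make_exact_outcomes <- function(n_intervention = 7, n_control = 6,
                                params = study_outcome_params()) {
  ids <- c(sprintf("i%02d", seq_len(n_intervention)),
           sprintf("c%02d", seq_len(n_control)))
  groups <- rep(c("intervention", "control"), c(n_intervention, n_control))
  purrr::map2_dfr(ids, groups, function(pid, grp) {
    p <- params[params$group == grp, ]
    tibble::tibble(patient_id = pid, group = grp, outcome_id = p$outcome_id,
                   baseline = p$baseline_mean, followup = p$followup_mean)
  })
}

# Independent rule-enumeration oracle for the zone algorithm: lists each
# zone's defining condition separately and returns the most severe zone
# whose condition holds (green otherwise).
zone_oracle <- function(delta_1d, delta_7d, severity) {
  d1 <- ifelse(is.na(delta_1d), -Inf, delta_1d)
  d7 <- ifelse(is.na(delta_7d), -Inf, delta_7d)
  conditions <- list(
    red = severity == "immediate",
    orange = severity == "moderate" && max(d1, d7) > 5,
    yellow = severity %in% c("mild", "moderate") || d1 >= 3 || d7 >= 5
  )
  for (z in c("red", "orange", "yellow")) {
    if (isTRUE(conditions[[z]])) return(z)
  }
  "green"
}

severity_grid <- c("stable", "mild", "moderate", "immediate")
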