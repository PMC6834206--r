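#' @title Seeded synthetic cohorts
#' @description
#' Generators for the three data shapes the analytic modules consume:
#' per-patient daily weight/symptom trajectories with fluid-retention
#' episodes plus Bernoulli app-access logs; blocked two-arm allocations; and
#' two-arm baseline/follow-up outcome tables with configurable group means
#' and SDs. Everything is reproducible from an integer seed.
#' @name synthetic-cohort
NULL

#' Default two-arm outcome parameters
#'
#' The study conditions used throughout the test-bench: per-outcome,
#' per-arm baseline and 30-day follow-up means and SDs for the seven pilot
#' outcomes (SCHFI maintenance/management/confidence on the raw-sum scale,
#' medication non-adherence, HF knowledge, quality of life, depression), as
#' observed in the 18-participant pilot.
#'
#' @return A tibble with columns `outcome_id`, `group`, `baseline_mean`,
#'   `baseline_sd`, `followup_mean`, `followup_sd`.
#' @export
study_outcome_params <- function() {
  tibble::tribble(
    ~outcome_id,            ~group,         ~baseline_mean, ~baseline_sd, ~followup_mean, ~followup_sd,
    "self_care_maintenance", "intervention", 22.86, 2.41, 28.29, 2.81,
    "self_care_maintenance", "control",      17.67, 3.61, 22.83, 5.56,
    "self_care_management",  "intervention", 12.00, 2.77, 20.71, 1.11,
    "self_care_management",  "control",       9.67, 2.66, 12.33, 3.03,
    "self_care_confidence",  "intervention", 12.43, 2.94, 19.46, 4.05,
    "self_care_confidence",  "control",      14.67, 3.01, 16.50, 2.07,
    "med_adherence",         "intervention",  3.00, 1.73,  3.23, 1.64,
    "med_adherence",         "control",       3.50, 1.65,  2.33, 1.50,
    "hf_knowledge",          "intervention", 24.29, 1.56, 27.28, 2.29,
    "hf_knowledge",          "control",      24.83, 2.13, 24.17, 1.71,
    "quality_of_life",       "intervention", 20.71, 9.09, 23.43, 6.50,
    "quality_of_life",       "control",      19.69, 7.64, 27.50, 8.52,
    "depression",            "intervention",  8.14, 5.60,  7.00, 6.13,
    "depression",            "control",       8.50, 5.36,  3.33, 2.94
  )
}

#' Blocked two-arm allocation sequence
#'
#' Randomizes participants to two arms in blocks. The per-arm block sizes
#' default to the pilot's alternating 3:3 / 2:2 pattern, cycled as needed.
#' Within each block the arm labels are randomly permuted; a final partial
#' block is drawn balanced (equal split when the remaining need is even),
#' so 18 participants under the default pattern always land 9 per arm. At
#' every prefix the arm imbalance is at most half the largest block.
#'
#' @param n Number of participants.
#' @param block_sizes Per-arm block sizes, cycled (default
#'   `c(3, 2, 3, 2, 3, 2, 3, 2)`).
#' @param groups The two arm labels.
#' @return Character vector of length `n` of arm labels, in enrollment
#'   order.
#' @export
block_allocation <- function(n, block_sizes = c(3, 2, 3, 2, 3, 2, 3, 2),
                             groups = c("intervention", "control")) {
  if (n < 1) abort("n must be at least 1")
  if (any(block_sizes < 1)) abort("block sizes must be positive")
  labels <- character(0)
  i <- 0
  while (length(labels) < n) {
    b <- block_sizes[(i %% length(block_sizes)) + 1]
    i <- i + 1
    need <- n - length(labels)
    if (need >= 2 * b) {
      block <- sample(rep(groups, each = b))
    } else {
      # balanced partial block: equal split, odd leftover to a random arm
      half <- need %/% 2
      extra <- if (need %% 2 == 1) sample(groups, 1) else character(0)
      block <- sample(c(rep(groups, each = half), extra))
    }
    labels <- c(labels, block)
  }
  labels
}

#' Simulate one patient's assessment history and access log
#'
#' Weight follows a Gaussian random walk around the baseline; a
#' fluid-retention episode starts on any day with probability
#' `episode_rate` (when none is active) and adds `episode_ramp` lb/day for
#' `episode_len` days. The day's symptom severity is linked to the trailing
#' 7-day weight gain through `severity_link` thresholds (gain below the
#' mild threshold reports stable, and so on). App access occurs on each day
#' independently with probability `adherence_p`; on an access day the
#' patient completes the daily assessment and visits one to three further
#' features.
#'
#' @param days Number of protocol days (default 30).
#' @param patient_id Identifier used in the output tables.
#' @param start_date First protocol day.
#' @param baseline_weight Starting weight in pounds.
#' @param daily_sd Random-walk step SD in pounds.
#' @param episode_rate Per-day probability that an episode starts.
#' @param episode_ramp Episode weight gain in lb/day.
#' @param episode_len Episode length in days.
#' @param adherence_p Daily app-access probability.
#' @param severity_link Named thresholds (lb of 7-day gain) for `mild`,
#'   `moderate`, `immediate` symptom reporting.
#' @param diuretic_prescribed Logical carried into the assessments.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return A list with `assessments` (one row per day: `patient_id`,
#'   `date`, `weight_lb`, `symptom_severity`, `sbp`, `dbp`, `hr`,
#'   `diuretic_prescribed`) and `events` (access log rows: `patient_id`,
#'   `timestamp`, `feature`).
#' @export
simulate_patient_history <- function(days = 30, patient_id = "p1",
                                     start_date = as.Date("2024-01-01"),
                                     baseline_weight = 180, daily_sd = 0.6,
                                     episode_rate = 0.05, episode_ramp = 1.5,
                                     episode_len = 4, adherence_p = 0.8,
                                     severity_link = c(mild = 3, moderate = 5,
                                                       immediate = 10),
                                     diuretic_prescribed = TRUE,
                                     seed = NULL) {
  if (days < 1) abort("days must be at least 1")
  if (daily_sd < 0 || episode_ramp < 0) abort("sds and ramps must be >= 0")
  if (episode_rate < 0 || episode_rate > 1 || adherence_p < 0 ||
      adherence_p > 1) {
    abort("episode_rate and adherence_p must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)

  steps <- rnorm(days, 0, daily_sd)
  episode_gain <- numeric(days)
  remaining <- 0
  for (t in seq_len(days)) {
    if (remaining == 0 && runif(1) < episode_rate) remaining <- episode_len
    if (remaining > 0) {
      episode_gain[t] <- episode_ramp
      remaining <- remaining - 1
    }
  }
  weight <- baseline_weight + cumsum(steps) + cumsum(episode_gain)
  weight <- pmax(weight, 1)

  gain_7d <- purrr::map_dbl(seq_len(days), function(t) {
    window <- weight[max(1, t - 6):t]
    weight[t] - min(window)
  })
  severity <- dplyr::case_when(
    gain_7d >= severity_link[["immediate"]] ~ "immediate",
    gain_7d >= severity_link[["moderate"]] ~ "moderate",
    gain_7d >= severity_link[["mild"]] ~ "mild",
    TRUE ~ "stable"
  )

  dates <- start_date + seq_len(days) - 1
  assessments <- tibble::tibble(
    patient_id = patient_id, date = dates, weight_lb = round(weight, 1),
    symptom_severity = severity,
    sbp = round(rnorm(days, 120, 8)), dbp = round(rnorm(days, 75, 6)),
    hr = round(rnorm(days, 72, 5)),
    diuretic_prescribed = diuretic_prescribed
  )

  accessed <- runif(days) < adherence_p
  events <- purrr::map(which(accessed), function(t) {
    extra_n <- sample(1:3, 1)
    feats <- c("ASSESSMENT", sample(setdiff(FEATURES, "ASSESSMENT"), extra_n))
    hours <- sort(round(runif(length(feats), 7, 21), 2))
    tibble::tibble(
      patient_id = patient_id,
      timestamp = sprintf("%sT%02d:%02d:00-05:00", format(dates[t]),
                          floor(hours), round((hours %% 1) * 60)),
      feature = feats
    )
  })
  events <- dplyr::bind_rows(events)
  if (nrow(events) == 0) {
    events <- tibble::tibble(patient_id = character(),
                             timestamp = character(), feature = character())
  }
  list(assessments = assessments, events = events)
}

#' Simulate a blocked two-arm outcome table
#'
#' Allocates `n_per_group` participants per arm with [block_allocation()]
#' and draws each participant's (baseline, follow-up) pair per outcome from
#' a bivariate normal with the configured marginal means/SDs and
#' within-patient correlation. Attrition is either completely at random at
#' `dropout_rate`, or fixed per-arm completer counts via `n_completers`
#' (non-completers keep their baseline and lose the follow-up).
#'
#' @param params Outcome parameter table, see [study_outcome_params()].
#' @param n_per_group Named integer vector of arm sizes (default 9 and 9).
#' @param correlation Within-patient baseline/follow-up correlation
#'   (default 0.5).
#' @param n_completers Optional named vector of completer counts per arm
#'   (e.g. `c(intervention = 7, control = 6)`); overrides `dropout_rate`.
#' @param dropout_rate Per-participant probability of missing follow-up
#'   (default 5/18).
#' @param block_sizes Passed to [block_allocation()].
#' @param seed Integer seed.
#' @return A list with `outcomes` (long table: `patient_id`, `group`,
#'   `outcome_id`, `baseline`, `followup`) and `allocation` (tibble
#'   `patient_id`, `group` in enrollment order).
#' @export
simulate_outcome_table <- function(params = study_outcome_params(),
                                   n_per_group = c(intervention = 9,
                                                   control = 9),
                                   correlation = 0.5,
                                   n_completers = NULL,
                                   dropout_rate = 5 / 18,
                                   block_sizes = c(3, 2, 3, 2, 3, 2, 3, 2),
                                   seed = NULL) {
  if (any(params$baseline_sd < 0) || any(params$followup_sd < 0)) {
    abort("SDs must be non-negative")
  }
  if (correlation < -1 || correlation > 1) {
    abort("correlation must lie in [-1, 1]")
  }
  if (any(n_per_group < 1)) abort("n_per_group must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  groups <- names(n_per_group)
  n <- sum(n_per_group)

  # draw blocked allocations until the requested arm sizes are hit
  # (the default 9:9 under the default pattern is balanced by construction)
  repeat {
    alloc <- block_allocation(n, block_sizes = block_sizes, groups = groups)
    if (all(table(factor(alloc, levels = groups)) == n_per_group)) break
  }
  allocation <- tibble::tibble(
    patient_id = sprintf("p%02d", seq_len(n)), group = alloc
  )

  completes <- if (!is.null(n_completers)) {
    done <- logical(n)
    for (g in groups) {
      idx <- which(alloc == g)
      done[sample(idx, min(n_completers[[g]], length(idx)))] <- TRUE
    }
    done
  } else {
    runif(n) >= dropout_rate
  }

  rho <- correlation
  rows <- purrr::pmap(
    list(allocation$patient_id, allocation$group, completes),
    function(pid, grp, done) {
      p <- params[params$group == grp, ]
      z1 <- rnorm(nrow(p)); z2 <- rnorm(nrow(p))
      baseline <- p$baseline_mean + p$baseline_sd * z1
      followup <- p$followup_mean +
        p$followup_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
      tibble::tibble(
        patient_id = pid, group = grp, outcome_id = p$outcome_id,
        baseline = baseline,
        followup = if (done) followup else NA_real_
      )
    }
  )
  list(outcomes = dplyr::bind_rows(rows), allocation = allocation)
}
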