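test_that("one-day delta matches the gain since the previous day's weight", {
  d1 <- as.Date("2024-03-01")
  h <- make_history(d1, 180)
  expect_equal(weight_deltas(h, 183, d1 + 1)$delta_1d, 3)
  same <- weight_deltas(h, 180, d1 + 1)
  expect_equal(same$delta_1d, 0)
  expect_equal(same$delta_7d, 0)
})

test_that("weekly delta uses the minimum weight in the trailing 7-day window", {
  d1 <- as.Date("2024-03-01")
  h <- make_history(c(d1, d1 + 2, d1 + 4), c(180, 181, 182.5))
  d <- weight_deltas(h, 185.5, d1 + 6)
  expect_equal(d$delta_7d, 5.5)
  expect_equal(d$ref_date_7d, d1)
})

test_that("weekly delta equals brute-force enumeration on random histories", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(1:10, 1)
    gaps <- sample(1:3, n, replace = TRUE)
    dates <- as.Date("2024-01-01") + cumsum(gaps)
    weights <- round(170 + cumsum(rnorm(n, 0, 1.5)), 1)
    today <- max(dates) + sample(1:3, 1)
    w_today <- round(weights[n] + rnorm(1), 1)
    h <- make_history(dates, weights)
    got <- weight_deltas(h, w_today, today)$delta_7d
    in_win <- dates > (today - 7) & dates < today
    want <- if (any(in_win)) w_today - min(weights[in_win]) else NA_real_
    expect_equal(got, want)
  }
})

test_that("missing-day weights carry forward up to the staleness limit", {
  d1 <- as.Date("2024-03-01")
  h <- make_history(d1, 180)
  # 4-day gap: yesterday's reference is 3 days stale -> still carried
  ok <- weight_deltas(h, 184, d1 + 4, staleness_days = 3)
  expect_equal(ok$delta_1d, 4)
  expect_false(ok$stale)
  # 5-day gap: beyond the limit, no 1-day delta
  stale <- weight_deltas(h, 184, d1 + 5, staleness_days = 3)
  expect_true(is.na(stale$delta_1d))
  expect_true(stale$stale)
})

test_that("empty history flags deltas missing; bad weights are rejected", {
  d <- weight_deltas(make_history(as.Date(character()), numeric()), 180,
                     as.Date("2024-03-01"))
  expect_true(is.na(d$delta_1d) && is.na(d$delta_7d))
  expect_error(weight_deltas(NULL, -1, as.Date("2024-03-01")), "positive")
  expect_error(
    weight_deltas(make_history(as.Date("2024-03-01"), 0), 180,
                  as.Date("2024-03-02")),
    "non-positive")
})

test_that("zone classification matches the spec'd wording on boundary cases", {
  expect_equal(as.character(classify_zone(0, 0, "stable")$zone), "green")
  expect_equal(as.character(classify_zone(NA, 6, "moderate")$zone), "orange")
  expect_equal(as.character(classify_zone(NA, NA, "immediate")$zone), "red")
  # gain of exactly 5 lb is yellow even with mild symptoms: orange needs
  # strictly more than 5
  expect_equal(as.character(classify_zone(NA, 5, "mild")$zone), "yellow")
  expect_equal(as.character(classify_zone(NA, 5, "moderate")$zone), "yellow")
  expect_equal(as.character(classify_zone(3, NA, "stable")$zone), "yellow")
  expect_equal(as.character(classify_zone(2.9, 4.9, "stable")$zone), "green")
})

test_that("classifier agrees with the rule-enumeration oracle on a lattice", {
  for (d1 in 0:8) for (d7 in 0:10) for (sev in severity_grid) {
    got <- as.character(classify_zone(d1, d7, sev)$zone)
    expect_equal(got, zone_oracle(d1, d7, sev),
                 info = sprintf("d1=%d d7=%d sev=%s", d1, d7, sev))
  }
})

test_that("zone is monotone in severity and in each delta", {
  zl <- c(green = 1, yellow = 2, orange = 3, red = 4)
  zn <- function(d1, d7, s) zl[[as.character(classify_zone(d1, d7, s)$zone)]]
  set.seed(7)
  for (rep in 1:40) {
    d1 <- runif(1, 0, 8); d7 <- runif(1, 0, 10)
    s <- sample(severity_grid, 1)
    si <- match(s, severity_grid)
    if (si < 4) expect_lte(zn(d1, d7, s), zn(d1, d7, severity_grid[si + 1]))
    expect_lte(zn(d1, d7, s), zn(d1 + runif(1, 0, 3), d7, s))
    expect_lte(zn(d1, d7, s), zn(d1, d7 + runif(1, 0, 3), s))
  }
})

test_that("classification is deterministic including rule ordering", {
  a <- classify_zone(4, 6, "moderate")
  b <- classify_zone(4, 6, "moderate")
  expect_identical(a$zone, b$zone)
  expect_identical(a$triggered_rules, b$triggered_rules)
  expect_true(length(a$triggered_rules[[1]]) > 1)
})

test_that("zone actions carry the program's feedback text and targets", {
  g <- zone_action("green")
  expect_equal(g$kind, "CONTINUE")
  expect_match(g$message, "continue current self-care practices")

  y_rx <- zone_action("yellow", diuretic_prescribed = TRUE)
  expect_match(y_rx$message, "extra dose of water pill")
  expect_match(y_rx$message, "call the home care staff")
  y_no <- zone_action("yellow", diuretic_prescribed = FALSE)
  expect_no_match(y_no$message, "water pill")
  expect_match(y_no$message, "call the home care staff")

  o <- zone_action("orange")
  expect_equal(o$kind, "CALL_PROVIDER")
  expect_true("coordinator" %in% o$notify_targets[[1]])

  r <- zone_action("red")
  expect_equal(r$kind, "EMERGENCY")
  expect_setequal(r$notify_targets[[1]],
                  c("emergency", "coordinator", "home_care"))
  expect_true(r$dry_run)
})

test_that("NYHA severity index follows the activity-limitation ladder", {
  resp <- function(rest, less, ord) {
    list(symptoms_at_rest = rest,
         symptoms_less_than_ordinary_activity = less,
         symptoms_ordinary_activity = ord)
  }
  expect_equal(as.character(severity_index(resp(TRUE, TRUE, TRUE))$nyha_class), "IV")
  expect_equal(as.character(severity_index(resp(FALSE, TRUE, TRUE))$nyha_class), "III")
  expect_equal(as.character(severity_index(resp(FALSE, FALSE, TRUE))$nyha_class), "II")
  expect_equal(as.character(severity_index(resp(FALSE, FALSE, FALSE))$nyha_class), "I")
  # pure: same inputs, same class
  expect_identical(severity_index(resp(FALSE, TRUE, TRUE)),
                   severity_index(resp(FALSE, TRUE, TRUE)))
  expect_error(severity_index(list(symptoms_at_rest = TRUE)), "missing")
})

test_that("per-item symptom answers escalate by the maximum item level", {
  expect_equal(symptom_severity_from_items(c("stable", "mild", "stable")),
               "mild")
  expect_equal(symptom_severity_from_items(c(0, 3, 1)), "immediate")
  expect_error(symptom_severity_from_items(numeric()), "at least one")
})

test_that("reminders fire only for active schedules inside the horizon", {
  sched <- tibble::tibble(
    medication = c("furosemide", "carvedilol", "lisinopril"),
    time = c("08:00", "20:00", "09:00"),
    active = c(TRUE, TRUE, FALSE)
  )
  now <- as.POSIXct("2024-03-01 07:00:00", tz = "UTC")
  one <- next_reminders(sched[1, ], now, 2)
  expect_equal(nrow(one), 1)
  expect_equal(format(one$fires_at, "%H:%M"), "08:00")

  # 24-h horizon from 07:00 covers today's 08:00 and 20:00 only
  # (tomorrow's 08:00 falls outside (now, now + 24h])
  day <- next_reminders(sched, now, 24)
  expect_equal(day$medication, c("furosemide", "carvedilol"))
  expect_true(all(diff(day$fires_at) > 0))
  wider <- next_reminders(sched, now, 26)
  expect_equal(wider$medication,
               c("furosemide", "carvedilol", "furosemide"))

  none <- next_reminders(sched[3, ], now, 24)
  expect_equal(nrow(none), 0)
  expect_error(next_reminders(sched, now, -1), "positive")
})

test_that("triage runs chronologically and collapses same-day duplicates", {
  a <- make_assessments(as.Date("2024-03-01") + c(0, 1, 1, 2),
                        c(180, 185, 182, 186), "stable")
  out <- triage(a)
  expect_equal(nrow(out), 3)              # duplicate day collapsed
  expect_equal(out$weight_lb[2], 182)     # last write wins
  expect_equal(out$delta_1d[3], 4)
  expect_identical(triage(a), triage(a))  # deterministic
})

test_that("triage escalates a ramping fluid-retention trajectory", {
  days <- as.Date("2024-03-01") + 0:6
  w <- c(180, 180, 180, 181.5, 183, 184.5, 186)   # 1.5 lb/day ramp from day 4
  out <- triage(make_assessments(days, w, "stable"))
  expect_equal(as.character(out$zone[4]), "green")
  expect_true(out$zone[7] >= "yellow")    # 6 lb over the window
})

test_that("kg weights convert to pounds on ingestion", {
  a <- tibble::tibble(patient_id = "p1", date = as.Date("2024-03-01"),
                      weight_kg = 180 / 2.20462, symptom_severity = "stable")
  out <- triage(a)
  expect_equal(out$weight_lb, 180)
})
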