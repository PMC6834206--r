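#' @title Two-arm pilot change-score analysis
#' @description
#' The pilot analysis compares intervention and control arms on per-patient
#' change scores (30-day score minus baseline score) with Student's
#' pooled-variance two-sample t-tests (df = n1 + n2 - 2; a completers
#' analysis with arms of 7 and 6 therefore has df = 11). Effect sizes are
#' partial eta squared, obtained by regressing the change score on a group
#' indicator: eta_p^2 = SS_effect / (SS_effect + SS_error), which for a
#' two-group comparison equals t^2 / (t^2 + df). Cohen's f =
#' sqrt(eta_p^2 / (1 - eta_p^2)) feeds the sample-size projection for a
#' larger trial.
#' @name pilot-statistics
NULL

#' Per-patient change scores
#'
#' Change is follow-up minus baseline. Rows with a missing endpoint
#' (non-completers) are dropped: the analysis set is completers-only, with
#' no imputation.
#'
#' @param outcomes A data frame with columns `patient_id`, `group`
#'   (`"intervention"`/`"control"`), `outcome_id`, `baseline`, `followup`.
#' @return The completer rows with an added `delta` column.
#' @export
change_scores <- function(outcomes) {
  required <- c("patient_id", "group", "outcome_id", "baseline", "followup")
  missing_cols <- setdiff(required, names(outcomes))
  if (length(missing_cols) > 0) {
    abort(sprintf("outcomes are missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  outcomes |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$baseline), !is.na(.data$followup)) |>
    dplyr::mutate(delta = .data$followup - .data$baseline)
}

#' Mean change score for one group and outcome
#'
#' Arithmetic mean of (follow-up - baseline) over completers; with complete
#' data it equals the difference of the group's follow-up and baseline
#' means.
#'
#' @inheritParams change_scores
#' @param group Group label to select.
#' @param outcome_id Outcome to select.
#' @return A single number.
#' @export
mean_change <- function(outcomes, group, outcome_id) {
  d <- change_scores(outcomes)
  d <- d[d$group == group & d$outcome_id == outcome_id, ]
  if (nrow(d) == 0) {
    abort(sprintf("no completers for outcome '%s' in group '%s'",
                  outcome_id, group))
  }
  mean(d$delta)
}

#' Student's pooled-variance two-sample t-test
#'
#' Pooled t on two vectors of change scores, with df = n1 + n2 - 2 and a
#' two-sided p-value. Zero pooled variance with equal means yields t = 0
#' (p = 1); zero pooled variance with different means yields an infinite t
#' (p = 0).
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return An object of class `pooled_t` with elements `statistic`, `df`,
#'   `p.value`, `estimate` (mean difference x - y), `mean_x`, `mean_y`,
#'   `n_x`, `n_y`, `pooled_sd`. [tidy()] and [glance()] methods return
#'   one-row tibbles.
#' @examples
#' tt <- pooled_t_test(c(1, 2, 3), c(4, 5, 6))
#' tidy(tt)
#' @export
pooled_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    abort(sprintf("each group needs at least 2 values (got %d and %d)",
                  n1, n2))
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  diff <- mean(x) - mean(y)
  if (sp2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    t <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  structure(
    list(statistic = t, df = df, p.value = p, estimate = diff,
         mean_x = mean(x), mean_y = mean(y), n_x = n1, n_y = n2,
         pooled_sd = sqrt(sp2)),
    class = "pooled_t"
  )
}

#' @export
print.pooled_t <- function(x, ...) {
  cat(sprintf("Pooled two-sample t-test: t(%d) = %0.3f, p = %0.4g\n",
              x$df, x$statistic, x$p.value))
  cat(sprintf("  mean difference %0.3f (means %0.3f vs %0.3f; n = %d, %d)\n",
              x$estimate, x$mean_x, x$mean_y, x$n_x, x$n_y))
  invisible(x)
}

#' @rdname pooled_t_test
#' @param x A `pooled_t` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pooled_t <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, estimate1 = x$mean_x, estimate2 = x$mean_y,
    statistic = x$statistic, p.value = x$p.value, parameter = x$df,
    method = "Pooled two-sample t-test", alternative = "two.sided"
  )
}

#' @rdname pooled_t_test
#' @exportS3Method generics::glance
glance.pooled_t <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p.value, df = x$df,
    n = x$n_x + x$n_y,
    partial_eta_sq = if (is.infinite(x$statistic)) 1 else {
      x$statistic^2 / (x$statistic^2 + x$df)
    }
  )
}

#' Partial eta squared from the group regression
#'
#' Fits the linear regression of the change score on a group indicator and
#' returns SS_effect / (SS_effect + SS_error). Degenerate cases: all values
#' identical gives 0; zero residual variance with differing group means
#' gives 1. For two groups this equals t^2 / (t^2 + df) from
#' [pooled_t_test()], an identity the test-suite verifies to 1e-10.
#'
#' @param x,y Numeric vectors of change scores for the two groups.
#' @return A value in \[0, 1\].
#' @export
partial_eta_squared <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 values")
  }
  # degenerate variance short-circuits (lm SS are floating noise there)
  if (var(c(x, y)) == 0) return(0)
  if (var(x) == 0 && var(y) == 0) return(1)   # means differ, zero residual
  d <- data.frame(delta = c(x, y),
                  group = rep(c("x", "y"), c(length(x), length(y))))
  fit <- lm(delta ~ group, data = d)
  a <- anova(fit)
  ss_eff <- a$`Sum Sq`[1]
  ss_err <- a$`Sum Sq`[2]
  if (ss_err == 0) return(1)
  ss_eff / (ss_eff + ss_err)
}

#' Cohen's f from partial eta squared
#'
#' @param partial_eta_sq Value in (0, 1).
#' @return Cohen's f = sqrt(eta / (1 - eta)).
#' @export
cohens_f <- function(partial_eta_sq) {
  if (any(partial_eta_sq <= 0 | partial_eta_sq >= 1)) {
    abort("partial_eta_sq must lie strictly between 0 and 1")
  }
  sqrt(partial_eta_sq / (1 - partial_eta_sq))
}

#' Sample-size projection from a pilot effect size
#'
#' Converts partial eta squared to Cohen's f and then to the two-group
#' standardized mean difference d = 2f, and sizes each arm with the
#' standard two-group normal-approximation formula
#' n = 2 ((z_(1-alpha/2) + z_power) / d)^2, rounded up, with a floor of 2
#' per arm.
#'
#' @param partial_eta_sq Pilot effect size in (0, 1).
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @param power Target power (default 0.80).
#' @return A one-row tibble: `partial_eta_sq`, `effect_size_f`, `cohens_d`,
#'   `alpha`, `power`, `n_per_group`, `n_total`.
#' @examples
#' sample_size(0.337)
#' @export
sample_size <- function(partial_eta_sq, alpha = 0.05, power = 0.80) {
  f <- cohens_f(partial_eta_sq)
  d <- 2 * f
  n <- ceiling(2 * ((qnorm(1 - alpha / 2) + qnorm(power)) / d)^2)
  n <- max(2L, as.integer(n))
  tibble::tibble(
    partial_eta_sq = partial_eta_sq, effect_size_f = f, cohens_d = d,
    alpha = alpha, power = power, n_per_group = n, n_total = 2L * n
  )
}

#' Completion (retention) percentage
#'
#' @param n_completed Number of participants completing follow-up.
#' @param n_randomized Number randomized.
#' @param digits Rounding for the returned percentage (default 0).
#' @return Percentage completed.
#' @examples
#' completion_percent(13, 18)  # 72
#' @export
completion_percent <- function(n_completed, n_randomized, digits = 0) {
  if (n_randomized <= 0) abort("n_randomized must be positive")
  round(100 * n_completed / n_randomized, digits)
}

#' Machine-readable outcome report for a two-arm pilot
#'
#' For every outcome in the table: group baseline and follow-up means and
#' SDs over completers, per-group mean change, pooled t, df, two-sided p,
#' and partial eta squared. This is the machine-readable twin of a
#' "baseline vs 30-day by arm" results table. Outcomes where either arm has
#' fewer than 2 completers are reported with `NA` statistics and a warning.
#'
#' @inheritParams change_scores
#' @param groups Character vector naming the two arms, first arm minus
#'   second in the t-test.
#' @return A tibble of class `hf_effect_report`, one row per outcome.
#' @export
outcome_report <- function(outcomes,
                           groups = c("intervention", "control")) {
  d <- change_scores(outcomes)
  if (nrow(d) == 0) abort("no completers in the outcome table")
  unknown <- setdiff(unique(d$group), groups)
  if (length(unknown) > 0) {
    abort(sprintf("unknown group label(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  one <- function(df) {
    g1 <- df[df$group == groups[1], ]
    g2 <- df[df$group == groups[2], ]
    base <- tibble::tibble(
      outcome_id = df$outcome_id[1],
      n_1 = nrow(g1), n_2 = nrow(g2),
      baseline_mean_1 = mean(g1$baseline), baseline_sd_1 = stats::sd(g1$baseline),
      followup_mean_1 = mean(g1$followup), followup_sd_1 = stats::sd(g1$followup),
      baseline_mean_2 = mean(g2$baseline), baseline_sd_2 = stats::sd(g2$baseline),
      followup_mean_2 = mean(g2$followup), followup_sd_2 = stats::sd(g2$followup),
      mean_change_1 = mean(g1$delta), mean_change_2 = mean(g2$delta)
    )
    if (nrow(g1) < 2 || nrow(g2) < 2) {
      rlang::warn(sprintf(
        "outcome '%s': fewer than 2 completers in an arm; statistics omitted",
        df$outcome_id[1]))
      return(dplyr::mutate(base, t_statistic = NA_real_, df = NA_integer_,
                           p_value = NA_real_, partial_eta_sq = NA_real_))
    }
    tt <- pooled_t_test(g1$delta, g2$delta)
    dplyr::mutate(base,
                  t_statistic = tt$statistic, df = as.integer(tt$df),
                  p_value = tt$p.value,
                  partial_eta_sq = partial_eta_squared(g1$delta, g2$delta))
  }
  rep <- d |>
    dplyr::group_split(.data$outcome_id) |>
    purrr::map(one) |>
    dplyr::bind_rows()
  names(rep) <- gsub("_1$", paste0("_", groups[1]), names(rep))
  names(rep) <- gsub("_2$", paste0("_", groups[2]), names(rep))
  class(rep) <- c("hf_effect_report", class(rep))
  attr(rep, "groups") <- groups
  rep
}

#' @rdname outcome_report
#' @param x An `hf_effect_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.hf_effect_report <- function(x, ...) {
  groups <- attr(x, "groups")
  tibble::tibble(
    n_outcomes = nrow(x),
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE),
    median_partial_eta_sq = stats::median(x$partial_eta_sq, na.rm = TRUE),
    groups = paste(groups, collapse = " vs ")
  )
}

#' @rdname outcome_report
#' @param object An `hf_effect_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.hf_effect_report <- function(object, ...) {
  groups <- attr(object, "groups")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("outcome_id",
                                  paste0("mean_change_", groups))],
    cols = -"outcome_id", names_to = "group", names_prefix = "mean_change_",
    values_to = "mean_change"
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$outcome_id, y = .data$mean_change,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean change (30-day minus baseline)",
                  fill = "Arm") +
    ggplot2::theme_minimal()
}
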