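#' Plot a performance-tracker trend series
#'
#' Line-and-point plot of a [trend_series()] with gaps preserved (no
#' interpolation across missing days).
#'
#' @param series A tibble with `date` and `value` columns.
#' @param metric Label for the y axis.
#' @return A ggplot object.
#' @export
plot_trend_series <- function(series, metric = "value") {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Plot per-patient engagement against the protocol window
#'
#' Bar chart of engagement percentages from [engagement_by_patient()],
#' with the low-engagement threshold drawn as a dashed line.
#'
#' @param summaries Engagement summary tibble.
#' @param low_threshold_pct Threshold line (default 50).
#' @return A ggplot object.
#' @export
plot_engagement <- function(summaries, low_threshold_pct = 50) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$patient_id,
                               y = .data$engagement_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = low_threshold_pct, linetype = "dashed") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "Engagement (% of protocol days active)") +
    ggplot2::theme_minimal()
}

#' Plot a patient's triage zones over time
#'
#' Tile strip of daily zones colored green/yellow/orange/red.
#'
#' @param triage_result A [triage()] result tibble.
#' @return A ggplot object.
#' @export
plot_zone_strip <- function(triage_result) {
  cols <- c(green = "#2e7d32", yellow = "#f9a825", orange = "#ef6c00",
            red = "#c62828")
  ggplot2::ggplot(triage_result,
                  ggplot2::aes(x = .data$date, y = .data$patient_id,
                               fill = .data$zone)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Zone") +
    ggplot2::theme_minimal()
}
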