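#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked activity-fraction bars
#'
#' Rest/low/high time fractions per session, the classic white/grey/black
#' stacked-bar rendering, faceted by placement.
#'
#' @param activity Activity tibble from [summarize_activity()] /
#'   [run_study()].
#' @return A ggplot object.
#' @export
plot_activity_fractions <- function(activity) {
  long <- tidyr::pivot_longer(
    activity, c("fraction_rest", "fraction_low", "fraction_high"),
    names_to = "level", names_prefix = "fraction_", values_to = "pct_time")
  long$level <- factor(long$level, levels = c("high", "low", "rest"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$session, SESSION_LEVELS),
    y = .data$pct_time, fill = .data$level)) +
    ggplot2::geom_col(colour = "black", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c(rest = "white", low = "grey70", high = "black")) +
    ggplot2::facet_grid(placement ~ animal) +
    ggplot2::labs(x = NULL, y = "% of time", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Activity recovery lines relative to Baseline
#'
#' @param activity Activity tibble with `recovery_pct`.
#' @return A ggplot object.
#' @export
plot_recovery <- function(activity) {
  df <- dplyr::filter(activity, !is.na(.data$recovery_pct))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$session, SESSION_LEVELS), y = .data$recovery_pct,
    group = .data$animal, colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~placement) +
    ggplot2::labs(x = NULL, y = "non-rest activity (% of Baseline)") +
    ggplot2::theme_minimal()
}

#' PTIBS score trajectories
#'
#' Per-animal traces with the group mean overlaid.
#'
#' @param assessments Tibble from [ptibs_assess()].
#' @return A ggplot object.
#' @export
plot_ptibs <- function(assessments) {
  grp <- ptibs_group_summary(assessments)
  ggplot2::ggplot(assessments, ggplot2::aes(
    x = factor(.data$session, SESSION_LEVELS), y = .data$score,
    group = .data$animal, colour = .data$group)) +
    ggplot2::geom_line(linetype = "dashed", alpha = 0.6) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grp, ggplot2::aes(
      y = .data$mean_score, group = .data$group), linewidth = 1) +
    ggplot2::scale_y_continuous(limits = c(1, 10), breaks = 1:10) +
    ggplot2::labs(x = NULL, y = "PTIBS score") +
    ggplot2::theme_minimal()
}

#' Mean +/- SEM normalized gait-cycle curve
#'
#' @param x A [representative_cycle()] or a `cycle_curves` tibble from
#'   [run_study()] (columns `pct`, `mean_angle`, `sem_angle` and optional
#'   grouping columns).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_gait_cycle <- function(x, ...) {
  df <- if (inherits(x, "representative_cycle")) x$curve else x
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$mean_angle)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_angle - .data$sem_angle,
      ymax = .data$mean_angle + .data$sem_angle), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "% of gait cycle", y = "hip angle (deg)") +
    ggplot2::theme_minimal()
  if (all(c("session", "side") %in% names(df))) {
    p <- p + ggplot2::aes(colour = .data$session, fill = .data$session) +
      ggplot2::facet_grid(side ~ animal)
  }
  p
}

#' @rdname plot_gait_cycle
#' @method autoplot representative_cycle
#' @export
autoplot.representative_cycle <- function(x, ...) plot_gait_cycle(x, ...)
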