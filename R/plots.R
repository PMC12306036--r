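# ggplot2 displays: per-age trajectories for prediction sets, score boxplots
# for studies, curvature functions for fits.

#' Plot predicted log-rate trajectories by age group
#'
#' One facet per age group; solid line is the point prediction, dashed lines
#' the interval, and the vertical dotted line marks where estimation stops
#' and forecasting begins.
#'
#' @param object An `apc_pred` tibble from `predict()`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apc_pred
#' @export
autoplot.apc_pred <- function(object, ...) {
  df <- as_tibble(object)
  cut <- if (any(df$forecast)) min(df$period[df$forecast]) - 0.5 else NA_real_
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$period)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$eta)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lwr), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upr), linetype = "dashed") +
    ggplot2::facet_wrap(~age, scales = "free_y") +
    ggplot2::labs(x = "period", y = "log rate")
  if (!is.na(cut)) {
    p <- p + ggplot2::geom_vline(xintercept = cut, linetype = "dotted")
  }
  p
}

#' Boxplots of per-replicate scores from a simulation study
#'
#' Interval score, interval width and empirical coverage per model, facetted
#' by estimation/forecasting window.
#'
#' @param object An `apc_study` from [run_simulation_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apc_study
#' @export
autoplot.apc_study <- function(object, ...) {
  long <- object$replicate_scores |>
    tidyr::pivot_longer(
      dplyr::all_of(c("is", "width", "coverage")),
      names_to = "score", values_to = "value"
    ) |>
    dplyr::mutate(score = factor(.data$score, c("is", "width", "coverage")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     fill = .data$model)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_grid(score ~ window, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot estimated curvature functions of a fitted APC model
#'
#' @param fit An `apc_spline` or `apc_rw2` fit.
#' @param level Interval level (default 0.95).
#' @return A ggplot with one facet per time scale.
#' @export
plot_curvatures <- function(fit, level = 0.95) {
  cv <- curvatures(fit, level = level)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$value, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_x") +
    ggplot2::labs(x = "index", y = "curvature")
}
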