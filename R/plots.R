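# ggplot2 views of the main result types.

#' Scatter of a feature across clinical categories
#'
#' The per-event feature (percent active minutes or mean SVM) jittered over
#' its clinical category, with the category-model boundaries as horizontal
#' lines — the standard view for judging how well the feature separates the
#' four activity levels.
#'
#' @param features Feature tibble from [event_features()].
#' @param value Feature column name (string).
#' @param model Optional [category_model()] whose boundaries are drawn.
#' @return A ggplot object.
#' @export
plot_category_scatter <- function(features, value = "pct_active",
                                  model = NULL) {
  p <- ggplot2::ggplot(features,
                       ggplot2::aes(x = factor(.data$category),
                                    y = .data[[value]])) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "Clinical activity category", y = value)
  if (!is.null(model)) {
    p <- p + ggplot2::geom_hline(yintercept = model$boundaries,
                                 linetype = "dashed", colour = "grey40")
  }
  p + ggplot2::theme_minimal()
}

#' Measured-vs-real step regression plot
#'
#' @param x A `step_regression` from [regress_steps()].
#' @param ... Unused.
#' @return A ggplot object with the fitted line and the R-squared annotated.
#' @exportS3Method
autoplot.step_regression <- function(x, ...) {
  df <- x$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predictor, y = .data$real)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Predictor", y = "Real steps per minute",
      subtitle = sprintf("R² = %.2f, n = %d", x$r_squared, x$n)) +
    ggplot2::theme_minimal()
}

#' Recovery comparison plot between timepoints
#'
#' Per-patient trajectories of one metric between the postoperative and
#' discharge timepoints, with group means overlaid.
#'
#' @param timepoints Timepoint tibble.
#' @param metric Column to plot (string).
#' @return A ggplot object.
#' @export
plot_recovery <- function(timepoints, metric = "active_minutes") {
  ggplot2::ggplot(timepoints,
                  ggplot2::aes(x = .data$timepoint_label,
                               y = .data[[metric]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          colour = "steelblue") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.agreement_report <- function(x, ...) {
  df <- tidy.agreement_report(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$clinical,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted category", y = "Clinical category",
                  subtitle = sprintf("Accuracy %.1f%%", 100 * x$accuracy)) +
    ggplot2::theme_minimal()
}
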