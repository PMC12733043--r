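# ggplot2 convenience plots for the fitted objects and datasets.

#' Plot a growth dataset
#'
#' Observed log10 counts over time, one colour per storage temperature;
#' censored observations are drawn as open triangles at the detection limit.
#'
#' @param data A growth dataset tibble.
#' @return A ggplot object.
#' @export
plot_growth_dataset <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$log10_count,
                                     colour = factor(.data$temperature))) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2),
                                guide = "none") +
    ggplot2::labs(x = "Storage time (days)",
                  y = expression(log[10] ~ "CFU/g"),
                  colour = "Temperature (°C)") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_one_step Fitted growth curves over the observed counts,
#'   one panel-free colour per temperature.
#' @param object A `growth_fit` object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  data <- object$data
  curves <- purrr::map_dfr(unique(data$temperature), function(tt) {
    grid <- seq(0, max(data$time[data$temperature == tt]), length.out = 100)
    tibble::tibble(
      temperature = tt, time = grid,
      log10_count = predict_log_count(object$params, object$variant, tt, grid)
    )
  })
  plot_growth_dataset(data) +
    ggplot2::geom_line(data = curves, linewidth = 0.7)
}

#' @describeIn fit_carotenoid_regression Scatter of carotenoid content vs
#'   colour index with the fitted line.
#' @param object A `carotenoid_fit` object.
#' @method autoplot carotenoid_fit
#' @export
autoplot.carotenoid_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ci, y = .data$caro)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = "Colour index", y = "Carotenoids (mg/kg FW)",
                  subtitle = sprintf("R² = %.2f, n = %d",
                                     object$r_squared, object$n)) +
    ggplot2::theme_minimal()
}
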