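#' Plot a fitted water-soaking time course
#'
#' Observed scores and the fitted lag-Gompertz curve, with the time lag
#' marked.
#'
#' @param object A [fit_gompertz()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gompertz_fit
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  grid <- tibble::tibble(time_h = seq(0, max(object$data$time_h), length.out = 200))
  grid$rating <- if (object$status == "no_symptoms") 0 else {
    gompertz_value(grid$time_h, object$asymptote, object$lag, object$rate)
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h, y = .data$rating)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$lag, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Incubation time (h)", y = "Water-soaking score",
                  title = sprintf("Gompertz fit: lag %.2f h, U %.2f /h, A %.2f",
                                  object$lag, object$rate, object$asymptote)) +
    ggplot2::theme_minimal()
}

#' Plot the water-soaking / log-permeance relationship
#'
#' Genotype means with the fitted regression line and the R-squared in
#' the title.
#'
#' @param object A [regress_ws_on_log_permeance()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ws_permeance_fit
#' @export
autoplot.ws_permeance_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$logp, y = .data$ws)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "log10 skin permeance (m/s)",
                  y = "Water-soaking score at index time",
                  title = sprintf("R² = %.1f%% (n = %d genotypes)",
                                  object$r_squared_pct, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a distribution report
#'
#' Histogram and normal-probability panel side by side.
#'
#' @param object A [distribution_report()] object.
#' @param ... Unused.
#' @return A ggplot (faceted).
#' @method autoplot distribution_report
#' @export
autoplot.distribution_report <- function(object, ...) {
  hist_df <- object$histogram |>
    dplyr::transmute(panel = "histogram", x = .data$mid, y = .data$count)
  qq_df <- object$qq |>
    dplyr::transmute(panel = "normal probability", x = .data$theoretical,
                     y = .data$sample)
  binw <- object$histogram$upper[1] - object$histogram$lower[1]
  ggplot2::ggplot() +
    ggplot2::geom_col(data = hist_df, ggplot2::aes(x = .data$x, y = .data$y),
                      fill = "steelblue", width = binw) +
    ggplot2::geom_point(data = qq_df, ggplot2::aes(x = .data$x, y = .data$y),
                        alpha = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
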