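# ggplot2 graphics for the main result types.

#' Plot rim intensity profiles
#'
#' @param profiles A [rim_profile()] tibble, or several bound together with
#'   a `channel` column.
#' @return A ggplot.
#' @export
plot_rim_profile <- function(profiles) {
  mapping <- if ("channel" %in% names(profiles)) {
    ggplot2::aes(x = .data$arc_um, y = .data$intensity, colour = .data$channel)
  } else {
    ggplot2::aes(x = .data$arc_um, y = .data$intensity)
  }
  ggplot2::ggplot(profiles, mapping) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc length (µm)", y = "mean intensity",
                  title = "Rim intensity profile") +
    ggplot2::theme_minimal()
}

#' Plot per-condition shape-index distributions
#'
#' @param morpho Per-nucleus morphometry tibble with a `condition` column.
#' @return A ggplot (one panel per index).
#' @export
plot_morphometry <- function(morpho) {
  long <- tidyr::pivot_longer(
    morpho[, c("condition", "circularity", "roundness", "solidity")],
    cols = c("circularity", "roundness", "solidity"),
    names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "red") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Nuclear shape descriptors") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a condition-level regression
#'
#' @param object A [group_linear_regression()] fit.
#' @param ... Unused.
#' @return A ggplot with the fitted line and annotation.
#' @export
autoplot.rim_regression <- function(object, ...) {
  g <- glance(object)
  lab <- sprintf("slope = %.3g, r² = %.2f, p = %.3g %s",
                 g$slope, g$r_squared, g$p_value, g$stars)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = object$x_name, y = object$y_name, subtitle = lab) +
    ggplot2::theme_minimal()
}
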