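# ggplot2 presentation of the pipeline's result types.

#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_col geom_point
#'   geom_rug annotate scale_fill_gradient2 scale_fill_viridis_c coord_equal
#'   labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Map a per-pixel trend field
#'
#' Diverging map of the cover-change slope (fraction per year): losses in
#' brown, gains in green, centred at zero.
#'
#' @param trend_map A `TrendMap` tibble from [pixel_trend()].
#' @param value Column to map (default `"slope"`).
#' @return A ggplot object.
#' @export
plot_trend_map <- function(trend_map, value = "slope") {
  ggplot(trend_map, aes(x = .data$x, y = .data$y, fill = .data[[value]])) +
    geom_raster() +
    scale_fill_gradient2(low = "#8c510a", mid = "#f6f6f1", high = "#01665e",
                         midpoint = 0) +
    coord_equal() +
    labs(fill = "slope\n(fraction/yr)",
         title = "Fractional woody cover change") +
    theme_minimal()
}

#' Plot landscape-mean cover per epoch with its trend line
#'
#' Mean fractional cover across pixels per epoch, plotted at the epoch
#' midpoints, with the OLS trend line dashed.
#'
#' @param cover_series A `CoverSeries` tibble (`epoch`, `cover`).
#' @param epochs Epoch table with `epoch` and `midpoint`.
#' @return A ggplot object.
#' @export
plot_cover_timeseries <- function(cover_series, epochs) {
  means <- cover_series %>%
    dplyr::group_by(.data$epoch) %>%
    dplyr::summarise(cover = mean(.data$cover, na.rm = TRUE), .groups = "drop") %>%
    dplyr::left_join(epochs[, c("epoch", "midpoint")], by = "epoch")
  fit <- ols_line(means$midpoint, means$cover)
  ggplot(means, aes(x = .data$midpoint, y = .data$cover)) +
    geom_line() + geom_point() +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         linetype = "dashed") +
    labs(x = "year (epoch midpoint)", y = "mean fractional woody cover",
         subtitle = sprintf("trend %.4f yr^-1 (p = %.3g)",
                            fit$slope, fit$p_value)) +
    theme_minimal()
}

#' Autoplot a driver model: relative importance bars
#'
#' @param object A `driver_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.driver_model <- function(object, ...) {
  imp <- relative_importance(object)
  imp$variable <- factor(imp$variable, levels = rev(imp$variable))
  ggplot(imp, aes(x = .data$importance, y = .data$variable)) +
    geom_col(fill = "#4d7c4d") +
    labs(x = "relative importance (%)", y = NULL,
         title = sprintf("CV deviance explained: %.0f%%",
                         100 * object$cv_deviance_explained)) +
    theme_minimal()
}

#' Autoplot a partial-dependence curve
#'
#' Fitted response across the 5th-95th percentile of the variable, with the
#' interquartile data band shaded and data deciles as a rug.
#'
#' @param object A `partial_dependence` from [partial_dependence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.partial_dependence <- function(object, ...) {
  iqr <- attr(object, "iqr")
  deciles <- attr(object, "deciles")
  ggplot(object, aes(x = .data$value, y = .data$yhat)) +
    annotate("rect", xmin = iqr[1], xmax = iqr[2], ymin = -Inf, ymax = Inf,
             fill = "grey85", alpha = 0.6) +
    geom_line(colour = "#b2182b", linewidth = 0.8) +
    geom_rug(data = tibble::tibble(value = deciles),
             aes(x = .data$value), inherit.aes = FALSE, sides = "b") +
    labs(x = object$variable[1], y = "fitted cover change") +
    theme_minimal()
}
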