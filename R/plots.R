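#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map a concentration field
#'
#' Raster map of daily-mean PM2.5, faceted by day.
#'
#' @param object A `conc_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conc_field
#' @export
autoplot.conc_field <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$pm25)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$day)) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "PM2.5\n(ug/m3)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("Daily-mean PM2.5,", format(object$scenario)),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Map an uncertainty field
#'
#' Diverging raster map of the signed absolute (default) or relative
#' uncertainty, faceted by day; masked relative cells are blank.
#'
#' @param object An `uncertainty_field`.
#' @param which `"absolute"` (ug m-3) or `"relative"` (%).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uncertainty_field
#' @export
autoplot.uncertainty_field <- function(object,
                                       which = c("absolute", "relative"),
                                       ...) {
  which <- match.arg(which)
  df <- as_tibble(object)
  unit <- if (which == "absolute") "ug/m3" else "%"
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data[[which]])) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$day)) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b",
                                  name = paste0(which, "\n(", unit, ")")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$factor, "uncertainty"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Observation-model scatter plot for paired monitor data
#'
#' Scatter of model versus observed PM2.5 with the 1:1 line and the OLS
#' fit whose slope and R-squared make up the evaluation statistics.
#'
#' @param pairs A pair tibble from [pair_monitors()].
#' @return A ggplot object.
#' @export
plot_evaluation <- function(pairs) {
  stopifnot(all(c("obs", "model") %in% names(pairs)))
  ggplot2::ggplot(pairs, ggplot2::aes(.data$obs, .data$model)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#b2182b") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Observed PM2.5 (ug/m3)", y = "Modeled PM2.5 (ug/m3)") +
    ggplot2::theme_minimal()
}

#' Forest plot of observed versus modeled incidence rate ratios
#'
#' @param object An `irr_comparison` tibble from [compare_irr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot irr_comparison
#' @export
autoplot.irr_comparison <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, region_id = .data$region_id, source = "observed",
                     irr = .data$observed_irr, lo = .data$observed_ci_low,
                     hi = .data$observed_ci_high),
    dplyr::transmute(object, region_id = .data$region_id, source = "modeled",
                     irr = .data$modeled_irr, lo = .data$modeled_ci_low,
                     hi = .data$modeled_ci_high)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$irr, .data$region_id,
                                     color = .data$source)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Incidence rate ratio (95% CI)", y = NULL,
                  color = NULL) +
    ggplot2::theme_minimal()
}
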