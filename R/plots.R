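#' Plot regional abundance trajectories from an IPM fit
#'
#' Posterior medians and 89% credible ribbons of the population state per
#' region-year.
#'
#' @param fit an `fc_ipm` object.
#' @return a ggplot object.
#' @export
plot_population <- function(fit) {
  d <- demographic_table(fit) |>
    dplyr::filter(.data$quantity == "n") |>
    dplyr::mutate(region = factor(.data$region))
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data$median,
                                  colour = .data$region,
                                  fill = .data$region)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower89,
                                      ymax = .data$upper89),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "Abundance index (n)",
                  colour = "Region", fill = "Region") +
    ggplot2::theme_minimal()
}

#' Plot annual demographic rates from an IPM fit
#'
#' @param fit an `fc_ipm` object.
#' @param quantity `"phi"` (survival) or `"gamma"` (recruitment rate).
#' @return a ggplot object.
#' @export
plot_rates <- function(fit, quantity = c("phi", "gamma")) {
  quantity <- match.arg(quantity)
  d <- demographic_table(fit) |>
    dplyr::filter(.data$quantity == .env$quantity) |>
    dplyr::mutate(region = factor(.data$region))
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data$median,
                                  colour = .data$region)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower89,
                                          ymax = .data$upper89),
                             position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(x = "Year",
                  y = if (quantity == "phi") "Adult apparent survival"
                      else "Recruitment rate",
                  colour = "Region") +
    ggplot2::theme_minimal()
}

#' Forest plot of climate covariate effects
#'
#' @param x an `fc_ipm` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fc_ipm <- function(x, ...) {
  d <- tidy.fc_ipm(x) |>
    dplyr::mutate(region = factor(.data$region))
  ggplot2::ggplot(d, ggplot2::aes(.data$median, .data$covariate,
                                  colour = .data$region)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower89,
                                          xmax = .data$upper89),
                             position = ggplot2::position_dodge(0.5)) +
    ggplot2::facet_wrap(~ .data$rate, scales = "free_x") +
    ggplot2::labs(x = "Effect (89% CrI)", y = NULL, colour = "Region") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a climate-vegetation regression
#'
#' @param data annual table with the two deviation columns.
#' @param response,covariate column names.
#' @return a ggplot object with the fitted line and 89% band.
#' @export
plot_climate_veg <- function(data, response, covariate) {
  ggplot2::ggplot(data, ggplot2::aes(.data[[covariate]],
                                     .data[[response]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = 0.89) +
    ggplot2::labs(x = covariate, y = response) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
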