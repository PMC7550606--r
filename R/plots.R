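# ggplot2 views of the main result types.

#' Plot classified tracks over the environmental grid
#'
#' @param states Classified state-series tibble.
#' @param env Optional [generate_env_grids()] object drawn as a depth
#'   raster with the land mask.
#' @return A ggplot object.
#' @export
plot_tracks <- function(states, env = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(env)) {
    g <- env_as_tibble(env)
    p <- p +
      ggplot2::geom_raster(
        data = g[!g$land, ],
        ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$depth)) +
      ggplot2::geom_raster(
        data = g[g$land, ],
        ggplot2::aes(x = .data$lon, y = .data$lat), fill = "grey30") +
      ggplot2::scale_fill_gradient(low = "#c6dbef", high = "#08306b",
                                   name = "depth (m)")
  }
  p +
    ggplot2::geom_path(
      data = states,
      ggplot2::aes(x = .data$lon, y = .data$lat, group = .data$segment),
      colour = "grey60", linewidth = 0.2) +
    ggplot2::geom_point(
      data = states,
      ggplot2::aes(x = .data$lon, y = .data$lat,
                   colour = .data$b_class), size = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(transit = "#1b9e77", uncertain = "grey50",
                 ARS = "#d95f02"), name = "behaviour") +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' @describeIn kaplan_meier_residency Step-curve plot of the residency
#'   probability with its quartile band.
#' @param object,x A `residency_curve`.
#' @param ... Unused.
#' @export
autoplot.residency_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_step(ggplot2::aes(y = .data$survival)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days since 10 September",
                  y = "probability of not having departed")
}

#' @describeIn fit_proportion_smooth Fitted proportion curve with its
#'   pointwise confidence band.
#' @param object A fitted `ars_smooth`.
#' @param ... Unused.
#' @export
autoplot.ars_smooth <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = object$covariate[1], y = "daily proportion ARS")
}

#' Diagnostic plot of the maximum coast distance per individual
#'
#' Shows the distribution whose bimodality motivates the departure rule's
#' offshore threshold; the chosen threshold is drawn as a dashed line.
#'
#' @param states Classified state series with `coast_dist` attached.
#' @param min_coast_km Threshold to draw.
#' @return A ggplot object.
#' @export
plot_max_coast_distance <- function(states, min_coast_km = 150) {
  d <- states |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(max_coast = max(.data$coast_dist, na.rm = TRUE))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$max_coast)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = min_coast_km, linetype = 2) +
    ggplot2::labs(x = "maximum distance to coast (km)",
                  y = "individuals")
}
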