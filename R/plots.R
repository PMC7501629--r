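#' Plot methods
#'
#' `autoplot()` methods render each result type with ggplot2: landscape and
#' isoscape surfaces as rasters, calibration posteriors as marginal
#' densities, and the direction-resolved detection distance as a polar
#' curve. [plot_hair_series()] draws per-animal segment profiles against
#' days before sampling.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name isomove_plots
NULL

#' @rdname isomove_plots
#' @method autoplot landscape_raster
#' @export
autoplot.landscape_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_km, .data$y_km,
                                       fill = .data$true_mean)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(delta^{34} * S ~ "(‰)")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = "True landscape δ³⁴S surface")
}

#' @rdname isomove_plots
#' @method autoplot isoscape_prediction
#' @export
autoplot.isoscape_prediction <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "x_km", "y_km",
                  "pred_mean", "pred_sd"),
    c("pred_mean", "pred_sd"),
    names_to = "surface", values_to = "value")
  long$surface <- dplyr::recode(long$surface,
                                pred_mean = "predicted mean",
                                pred_sd = "prediction SD (σ_L)")
  ggplot2::ggplot(long, ggplot2::aes(.data$x_km, .data$y_km,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~surface, scales = "free") +
    ggplot2::scale_fill_viridis_c(name = "‰") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = "Predicted δ³⁴S isoscape")
}

#' @rdname isomove_plots
#' @method autoplot calibration_posterior
#' @export
autoplot.calibration_posterior <- function(object, ...) {
  core <- intersect(c("beta", "alpha", "sigma_eps", "sigma_alpha", "sigma_M"),
                    names(object$draws))
  long <- tidyr::pivot_longer(object$draws[core], dplyr::everything(),
                              names_to = "param", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = "Calibration posterior marginals")
}

#' @rdname isomove_plots
#' @method autoplot detection_polar
#' @export
autoplot.detection_polar <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::bind_rows(df, dplyr::mutate(df[df$bearing_deg == min(df$bearing_deg), ],
                                           bearing_deg = 360 + .data$bearing_deg))
  ggplot2::ggplot(df, ggplot2::aes(.data$bearing_deg, .data$detection_km)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored)) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(breaks = c(0, 90, 180, 270),
                                labels = c("N", "E", "S", "W"),
                                limits = c(0, 360)) +
    ggplot2::labs(x = NULL, y = "detection distance (km)",
                  title = "Distance needed to detect movement, by bearing",
                  shape = "censored")
}

#' @rdname isomove_plots
#' @param hair Hair tibble with `animal_id`, `start_day`, `end_day` and
#'   `d34S_permil`.
#' @export
plot_hair_series <- function(hair, ...) {
  mid <- (hair$start_day + hair$end_day) / 2
  ggplot2::ggplot(dplyr::mutate(hair, day_mid = mid),
                  ggplot2::aes(.data$day_mid, .data$d34S_permil)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~animal_id) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "days before sampling",
                  y = expression(delta^{34} * S[hair] ~ "(‰)"),
                  title = "Tail-hair δ³⁴S series (root at day 0)")
}
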