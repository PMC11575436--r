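#' Plot a track over an optional raster
#'
#' @param track A track tibble.
#' @param grid Optional background [raster_grid()].
#' @return A ggplot object.
#' @export
plot_track <- function(track, grid = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(grid)) {
    cc <- cell_centers(grid$spec)
    cc$value <- grid$values
    p <- p + ggplot2::geom_raster(
      data = cc, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
      ggplot2::scale_fill_viridis_c()
  }
  p +
    ggplot2::geom_path(data = track,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.3, colour = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' @export
autoplot.raster_grid <- function(object, ...) {
  cc <- cell_centers(object$spec)
  cc$value <- object$values
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "value")
}

#' @export
autoplot.ssf_fit <- function(object, conf.level = 0.95, ...) {
  td <- tidy(object, conf.int = TRUE, conf.level = conf.level)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "coefficient", y = NULL)
}

#' Plot a relative-selection-strength curve
#'
#' @param curve Output of [rss_curve()].
#' @param xlab X-axis label.
#' @return A ggplot object.
#' @export
plot_rss_curve <- function(curve, xlab = "covariate value") {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$value, y = .data$rss))
  if (all(c("conf.low", "conf.high") %in% names(curve))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "relative selection strength")
}
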