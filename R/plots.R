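#' Quick side-view plot of a point cloud
#'
#' Plots the x-z projection; with RGB columns present the stored colors are
#' used, otherwise points are shaded by height.
#'
#' @param cloud A point-cloud tibble.
#' @param max_points Random subsample cap for plotting speed.
#' @param size Point size.
#' @return A ggplot object.
#' @export
plot_cloud <- function(cloud, max_points = 30000, size = 0.3) {
  validate_cloud(cloud)
  if (nrow(cloud) > max_points) {
    cloud <- cloud[sample.int(nrow(cloud), max_points), ]
  }
  p <- ggplot2::ggplot(cloud, ggplot2::aes(x = .data$x, y = .data$z))
  if (has_colors(cloud)) {
    cols <- grDevices::rgb(cloud$r, cloud$g, cloud$b, maxColorValue = 255)
    p <- p + ggplot2::geom_point(colour = cols, size = size)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$z), size = size) +
      ggplot2::scale_colour_viridis_c()
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "z (cm)") +
    ggplot2::theme_minimal()
}

#' Color-margin histograms
#'
#' G-R and G-B frequency distributions of a colored cloud with the filtering
#' thresholds marked; wheat tissue sits to the right of both lines.
#'
#' @param cloud A colored point-cloud tibble.
#' @param gr_thresh,gb_thresh Thresholds to mark.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_color_margins <- function(cloud, gr_thresh = 5, gb_thresh = 30, bins = 60) {
  h <- color_margin_histogram(cloud, bins = bins)
  vl <- tibble(margin = c("G-R", "G-B"), thr = c(gr_thresh, gb_thresh))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(range(h$mid)) / bins, fill = "grey40") +
    ggplot2::geom_vline(data = vl, ggplot2::aes(xintercept = .data$thr),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_wrap(~margin, scales = "free") +
    ggplot2::labs(x = "channel difference", y = "points") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trait_metrics <- function(object, ...) {
  lab <- object$metrics |>
    dplyr::mutate(label = sprintf("R² = %.4f\nRMSE = %.4g",
                                  .data$r_squared, .data$rmse))
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$y, y = .data$yhat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.1, vjust = 1.2,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "reference value", y = "extracted value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.growth_dynamics <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$stage, y = .data$mean,
                               colour = .data$cultivar,
                               group = .data$cultivar)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             size = 0.3) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.segmentation_result <- function(object, cloud, ...) {
  validate_cloud(cloud)
  dd <- dplyr::mutate(cloud, region = factor(object$labels))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$x, y = .data$z,
                                   colour = .data$region)) +
    ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "z (cm)") +
    ggplot2::theme_minimal()
}
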