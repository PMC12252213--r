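#' @export
#' @method autoplot sdm_raster
autoplot.sdm_raster <- function(object, ...) {
  df <- cells(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data[[object$name]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$name, x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot response_curve
autoplot.response_curve <- function(object, level = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                            y = .data$suitability)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = object$variable[1], y = "Predicted suitability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(level))
    p <- p + ggplot2::geom_hline(yintercept = level, linetype = 2)
  p
}

#' @export
#' @method autoplot centroid_track
autoplot.centroid_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_path(arrow = grid::arrow(length = grid::unit(2, "mm")),
                       colour = "grey40") +
    ggplot2::geom_point(size = 2, colour = "#b2182b") +
    ggplot2::geom_text(ggplot2::aes(label = .data$scenario),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = "Suitable-habitat centroid migration") +
    ggplot2::theme_minimal()
}

#' Bar chart of suitability-class areas by scenario
#'
#' @param areas The `areas` tibble from [scenario_report()].
#' @return A ggplot object.
#' @export
plot_class_areas <- function(areas) {
  long <- tidyr::pivot_longer(
    areas[, c("scenario", "area_low", "area_medium", "area_high")],
    cols = -"scenario", names_to = "class", values_to = "area")
  long$class <- factor(sub("area_", "", long$class),
                       levels = c("low", "medium", "high"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$area,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(low = "#fee08b", medium = "#fc8d59",
                                          high = "#d73027")) +
    ggplot2::labs(x = NULL, y = expression("Area (" * 10^4 ~ km^2 * ")"),
                  fill = "Suitability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
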