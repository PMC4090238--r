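# ggplot2 helpers for the package's result types.

#' Plot an origin-risk map
#'
#' Draws the out-of-jurisdiction origin-risk surface as tiles at cell
#' centres, coloured by risk on a log10 scale (relative risk values span
#' orders of magnitude).
#'
#' @param object An `origin_risk_map` from [jurisdiction_origin_risk()].
#' @param grid The [grid_spec()] the cell ids refer to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.origin_risk_map <- function(object, grid, ...) {
  stopifnot(inherits(grid, "grid_spec"))
  jur <- attr(object, "jurisdiction")
  df <- dplyr::bind_cols(
    cell_center(grid, object$cell)[c("lon", "lat")],
    risk = object$risk
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$risk)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10", name = "summed φ") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(
      title = paste0("External origin risk: ", jur$name),
      x = "longitude", y = "latitude"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a forward or reverse pathway profile
#'
#' Bar chart of the top-ranked cells in a pathway profile.
#'
#' @param profile A tibble from [forward_profile()] or [reverse_profile()].
#' @param top Number of cells to show. Default 20.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, top = 20) {
  df <- utils::head(profile, top)
  df$cell <- factor(df$cell, levels = rev(df$cell))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$risk, y = .data$cell)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "relative risk φ", y = "cell id") +
    ggplot2::theme_minimal()
}

#' Plot the trip-distance distribution of a trip set
#'
#' Histogram of one-way great-circle trip distances with the two reference
#' quantile markers (100 km and 500 km) that anchor the default kernel.
#'
#' @param trips A trip tibble.
#' @param bins Histogram bins. Default 60.
#' @return A ggplot object.
#' @export
plot_trip_distances <- function(trips, bins = 60) {
  df <- tibble::tibble(distance = trip_distances(trips))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(100, 500), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "one-way trip distance (km)", y = "trips") +
    ggplot2::theme_minimal()
}
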