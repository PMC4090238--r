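# Equal-area grid over a lon/lat extent.
#
# Points are projected with a spherical Lambert azimuthal equal-area (LAEA)
# projection centred on the extent, then binned into square cells of
# `cell_size` km. Cell ids are row-major integers counted from the grid's
# lower-left corner, so the lon/lat -> cell mapping is deterministic and
# invertible to a cell-centre point.

EARTH_RADIUS_KM <- 6371.0088

#' Define an equal-area analysis grid
#'
#' Creates the grid specification used to aggregate origin-destination trip
#' records into network nodes. Points are projected with a spherical Lambert
#' azimuthal equal-area projection centred on the extent (configurable), and
#' binned into square cells; the default cell size is 15 km, the resolution
#' at which reservation data are coarsened into map cells.
#'
#' @param extent Named numeric vector or list with `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max` (degrees).
#' @param cell_size Cell edge length in km (> 0). Default 15.
#' @param lon0,lat0 Projection centre in degrees; defaults to the extent
#'   centre.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(lon_min = -90, lon_max = -80, lat_min = 30, lat_max = 36))
#' id <- cell_of(g, -85, 33)
#' cell_center(g, id)
#' @export
grid_spec <- function(extent, cell_size = 15, lon0 = NULL, lat0 = NULL) {
  extent <- as.list(extent)
  need <- c("lon_min", "lon_max", "lat_min", "lat_max")
  if (!all(need %in% names(extent))) {
    stop("`extent` must supply ", paste(need, collapse = ", "), call. = FALSE)
  }
  extent <- lapply(extent[need], as.numeric)
  if (extent$lon_min >= extent$lon_max || extent$lat_min >= extent$lat_max) {
    stop("degenerate extent: min must be below max on both axes", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number (km)", call. = FALSE)
  }
  if (is.null(lon0)) lon0 <- (extent$lon_min + extent$lon_max) / 2
  if (is.null(lat0)) lat0 <- (extent$lat_min + extent$lat_max) / 2

  # Projected bounding box of the extent rectangle: sample the boundary
  # densely because under LAEA the extremes can fall on edges, not corners.
  s <- seq(0, 1, length.out = 33)
  edge <- rbind(
    cbind(extent$lon_min + s * (extent$lon_max - extent$lon_min), extent$lat_min),
    cbind(extent$lon_min + s * (extent$lon_max - extent$lon_min), extent$lat_max),
    cbind(extent$lon_min, extent$lat_min + s * (extent$lat_max - extent$lat_min)),
    cbind(extent$lon_max, extent$lat_min + s * (extent$lat_max - extent$lat_min))
  )
  xy <- laea_project(edge[, 1], edge[, 2], lon0, lat0)
  pad <- 1e-9 * max(1, max(abs(xy$x)), max(abs(xy$y)))
  x0 <- min(xy$x) - pad
  y0 <- min(xy$y) - pad
  ncols <- max(1L, as.integer(ceiling((max(xy$x) + pad - x0) / cell_size)))
  nrows <- max(1L, as.integer(ceiling((max(xy$y) + pad - y0) / cell_size)))

  structure(
    list(
      extent = extent, cell_size = cell_size, lon0 = lon0, lat0 = lat0,
      x0 = x0, y0 = y0, ncols = ncols, nrows = nrows,
      radius_km = EARTH_RADIUS_KM
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g km (LAEA centre %.3f, %.3f)\n",
    x$nrows, x$ncols, x$cell_size, x$lon0, x$lat0
  ))
  cat(sprintf(
    "  extent lon [%g, %g], lat [%g, %g]\n",
    x$extent$lon_min, x$extent$lon_max, x$extent$lat_min, x$extent$lat_max
  ))
  invisible(x)
}

# Spherical forward LAEA: lon/lat degrees -> km east/north of (lon0, lat0).
laea_project <- function(lon, lat, lon0, lat0, R = EARTH_RADIUS_KM) {
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- lat0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  # denom -> 0 only at the antipode of the projection centre
  k <- sqrt(2 / pmax(denom, 1e-12))
  list(
    x = R * k * cos(phi) * sin(lam),
    y = R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam))
  )
}

# Inverse LAEA: km east/north -> lon/lat degrees.
laea_unproject <- function(x, y, lon0, lat0, R = EARTH_RADIUS_KM) {
  phi0 <- lat0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * R)))
  sinc <- sin(c_ang)
  cosc <- cos(c_ang)
  phi <- ifelse(
    rho < 1e-12, phi0,
    asin(pmin(1, pmax(-1, cosc * sin(phi0) + y * sinc * cos(phi0) / pmax(rho, 1e-12))))
  )
  lam <- ifelse(
    rho < 1e-12, 0,
    atan2(x * sinc, rho * cos(phi0) * cosc - y * sin(phi0) * sinc)
  )
  list(lon = lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}

#' Map points to grid cell ids
#'
#' Projects lon/lat points and returns the row-major integer id of the cell
#' each point falls in. The mapping is deterministic; each point in the grid
#' extent maps to exactly one cell.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Numeric vectors of coordinates in degrees.
#' @return Integer vector of cell ids.
#' @export
cell_of <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"))
  xy <- laea_project(lon, lat, grid$lon0, grid$lat0)
  col <- floor((xy$x - grid$x0) / grid$cell_size)
  row <- floor((xy$y - grid$y0) / grid$cell_size)
  bad <- which(col < 0 | col >= grid$ncols | row < 0 | row >= grid$nrows |
                 !is.finite(col) | !is.finite(row))
  if (length(bad) > 0) {
    stop(
      "point outside grid extent at position ", bad[1],
      sprintf(" (lon %g, lat %g)", lon[bad[1]], lat[bad[1]]),
      call. = FALSE
    )
  }
  as.integer(row * grid$ncols + col + 1)
}

#' Cell centre coordinates for cell ids
#'
#' Inverse of [cell_of()]: returns the lon/lat of each cell's centre point.
#'
#' @param grid A [grid_spec()].
#' @param id Integer vector of cell ids.
#' @return A tibble with columns `cell`, `lon`, `lat`.
#' @export
cell_center <- function(grid, id) {
  stopifnot(inherits(grid, "grid_spec"))
  id <- as.integer(id)
  if (any(id < 1 | id > grid$ncols * grid$nrows, na.rm = TRUE) || anyNA(id)) {
    stop("cell id out of range for this grid", call. = FALSE)
  }
  row <- (id - 1L) %/% grid$ncols
  col <- (id - 1L) %% grid$ncols
  x <- grid$x0 + (col + 0.5) * grid$cell_size
  y <- grid$y0 + (row + 0.5) * grid$cell_size
  ll <- laea_unproject(x, y, grid$lon0, grid$lat0)
  tibble::tibble(cell = id, lon = ll$lon, lat = ll$lat)
}

#' Serialise / restore a grid specification
#'
#' The grid travels with run metadata as a small JSON block so that exported
#' risk maps can be re-joined to geography later.
#'
#' @param grid A [grid_spec()].
#' @param path File path for the JSON.
#' @return `write_grid_spec()` returns `path` invisibly; `read_grid_spec()`
#'   returns the restored `grid_spec`.
#' @export
write_grid_spec <- function(grid, path) {
  stopifnot(inherits(grid, "grid_spec"))
  jsonlite::write_json(
    unclass(grid), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_grid_spec
#' @export
read_grid_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- grid_spec(
    extent = raw$extent, cell_size = raw$cell_size,
    lon0 = raw$lon0, lat0 = raw$lat0
  )
  # restore the exact stored frame rather than recomputing it
  g$x0 <- raw$x0; g$y0 <- raw$y0
  g$ncols <- as.integer(raw$ncols); g$nrows <- as.integer(raw$nrows)
  g
}
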