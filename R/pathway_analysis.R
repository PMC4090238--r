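# Decision products built from a risk matrix: forward and reverse pathway
# profiles, jurisdiction-level origin-risk maps, and hotspot classification.

#' Forward pathway profile: likeliest destinations from an origin
#'
#' Returns all destinations with positive risk from `origin` (row i of the
#' risk matrix), sorted by descending risk; ties break by ascending cell id
#' for determinism.
#'
#' @param phi A `risk_matrix` from [estimate_phi()].
#' @param origin Origin cell id; must appear among the simulated origins.
#' @return A tibble with columns `cell` and `risk`.
#' @export
forward_profile <- function(phi, origin) {
  stopifnot(inherits(phi, "risk_matrix"))
  if (length(origin) != 1L || !origin %in% attr(phi, "origins")) {
    stop("origin ", origin[1], " is not in the risk matrix", call. = FALSE)
  }
  out <- phi |>
    tibble::as_tibble() |>
    dplyr::filter(.data$cell_i == origin, .data$phi > 0) |>
    dplyr::arrange(dplyr::desc(.data$phi), .data$cell_j)
  tibble::tibble(cell = out$cell_j, risk = out$phi)
}

#' Reverse pathway profile: likeliest origins for a destination
#'
#' Returns all origins with positive risk toward `destination` (column j of
#' the risk matrix), sorted by descending risk; ties break by ascending cell
#' id.
#'
#' @param phi A `risk_matrix`.
#' @param destination Destination cell id; must be a cell of the matrix.
#' @return A tibble with columns `cell` and `risk`.
#' @export
reverse_profile <- function(phi, destination) {
  stopifnot(inherits(phi, "risk_matrix"))
  known <- unique(c(attr(phi, "origins"), phi$cell_j))
  if (length(destination) != 1L || !destination %in% known) {
    stop("destination ", destination[1], " is not in the risk matrix",
         call. = FALSE)
  }
  out <- phi |>
    tibble::as_tibble() |>
    dplyr::filter(.data$cell_j == destination, .data$phi > 0) |>
    dplyr::arrange(dplyr::desc(.data$phi), .data$cell_i)
  tibble::tibble(cell = out$cell_i, risk = out$phi)
}

#' Define a jurisdiction (state or province)
#'
#' A jurisdiction is a named set of grid cells, given either explicitly or
#' derived from a boundary polygon: a cell belongs to the jurisdiction when
#' its centre point falls inside the polygon, so border cells belong to
#' exactly one jurisdiction.
#'
#' @param name Jurisdiction name or code.
#' @param cells Integer vector of member cell ids (mutually exclusive with
#'   `polygon`).
#' @param polygon Two-column matrix or data frame of boundary vertices
#'   (`lon`, `lat`); requires `grid`.
#' @param grid A [grid_spec()], needed when `polygon` is given. Candidate
#'   cells default to every cell of the grid; pass `candidates` to restrict.
#' @param candidates Optional integer vector of cell ids to test against the
#'   polygon.
#' @return An object of class `jurisdiction` with fields `name` and `cells`.
#' @export
jurisdiction <- function(name, cells = NULL, polygon = NULL, grid = NULL,
                         candidates = NULL) {
  if (is.null(cells) == is.null(polygon)) {
    stop("supply exactly one of `cells` or `polygon`", call. = FALSE)
  }
  if (!is.null(polygon)) {
    if (is.null(grid)) stop("`polygon` requires `grid`", call. = FALSE)
    stopifnot(inherits(grid, "grid_spec"))
    poly <- as.matrix(as.data.frame(polygon)[, 1:2])
    if (is.null(candidates)) candidates <- seq_len(grid$ncols * grid$nrows)
    ctr <- cell_center(grid, candidates)
    inside <- mgcv::in.out(poly, cbind(ctr$lon, ctr$lat))
    cells <- candidates[inside]
  }
  cells <- sort(unique(as.integer(cells)))
  if (length(cells) == 0L) {
    stop("jurisdiction '", name, "' has an empty member set", call. = FALSE)
  }
  structure(list(name = as.character(name), cells = cells),
            class = "jurisdiction")
}

#' @export
print.jurisdiction <- function(x, ...) {
  cat(sprintf("<jurisdiction> %s: %d cells\n", x$name, length(x$cells)))
  invisible(x)
}

#' Out-of-jurisdiction origin-risk map
#'
#' For a target jurisdiction S, sums the dispersal risk from every external
#' cell i into the jurisdiction: `risk(i) = sum_{j in S} phi_ij` for all
#' `i` not in S with a positive sum. This is the per-state summary map of
#' the likeliest external source locations for a camper-transported pest
#' found inside the target. It equals, exactly, the external-origin sum of
#' the member cells' reverse profiles.
#'
#' @param phi A `risk_matrix`.
#' @param target A [jurisdiction()] whose member set intersects the matrix
#'   node set.
#' @return An `origin_risk_map`: tibble with columns `cell` and `risk`
#'   (descending, ties by ascending cell id), with the target stored as an
#'   attribute.
#' @export
jurisdiction_origin_risk <- function(phi, target) {
  stopifnot(inherits(phi, "risk_matrix"), inherits(target, "jurisdiction"))
  nodes <- unique(c(phi$cell_i, phi$cell_j, attr(phi, "origins")))
  if (!any(target$cells %in% nodes)) {
    stop("jurisdiction '", target$name,
         "' does not intersect the risk matrix node set", call. = FALSE)
  }
  out <- phi |>
    tibble::as_tibble() |>
    dplyr::filter(.data$cell_j %in% target$cells,
                  !(.data$cell_i %in% target$cells)) |>
    dplyr::group_by(cell = .data$cell_i) |>
    dplyr::summarise(risk = sum(.data$phi), .groups = "drop") |>
    dplyr::filter(.data$risk > 0) |>
    dplyr::arrange(dplyr::desc(.data$risk), .data$cell)
  structure(tibble::tibble(cell = out$cell, risk = out$risk),
            jurisdiction = target,
            class = c("origin_risk_map", class(tibble::tibble())))
}

#' @export
print.origin_risk_map <- function(x, ...) {
  j <- attr(x, "jurisdiction")
  cat(sprintf("<origin_risk_map> target %s: %d external source cells\n",
              j$name, nrow(x)))
  NextMethod()
}

#' Classify origin-risk values into hotspot classes
#'
#' Labels each positive-risk cell: `"moderate-high"` where the summed risk
#' strictly exceeds the hotspot threshold (default 0.0001, the cutoff used
#' to call moderate-to-high-risk hotspots), `"low"` otherwise. Zero-risk
#' cells are absent by construction.
#'
#' @param values An `origin_risk_map` (or tibble with `cell`, `risk`).
#' @param hotspot_threshold Strictly positive threshold; risk must exceed it
#'   (strict inequality) to be labelled `"moderate-high"`.
#' @return The input with an added `class` column.
#' @export
classify_risk <- function(values, hotspot_threshold = 0.0001) {
  if (!is.numeric(hotspot_threshold) || length(hotspot_threshold) != 1L ||
      hotspot_threshold <= 0) {
    stop("`hotspot_threshold` must be a single positive number", call. = FALSE)
  }
  values$class <- ifelse(values$risk > hotspot_threshold, "moderate-high", "low")
  values
}

#' Export an origin-risk map
#'
#' Writes the map as CSV (`cell`, `lon`, `lat`, `risk`, and `class` when
#' present) using the grid to recover cell-centre coordinates, or as GeoJSON
#' with one square cell polygon per feature. CSV values round-trip exactly
#' through [read_risk_map()].
#'
#' @param map An `origin_risk_map` (optionally classified).
#' @param grid The [grid_spec()] the cell ids refer to.
#' @param path Output file path.
#' @param format `"csv"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
export_risk_map <- function(map, grid, path, format = c("csv", "geojson")) {
  stopifnot(inherits(grid, "grid_spec"))
  format <- match.arg(format)
  has_class <- "class" %in% names(map)
  if (nrow(map) > 0) {
    ctr <- cell_center(grid, map$cell)
    df <- tibble::tibble(cell = map$cell, lon = ctr$lon, lat = ctr$lat,
                         risk = map$risk)
  } else {
    df <- tibble::tibble(cell = integer(), lon = double(), lat = double(),
                         risk = double())
  }
  if (has_class) df$class <- map$class

  if (format == "csv") {
    readr::write_csv(df, path)
    return(invisible(path))
  }

  features <- purrr::map(seq_len(nrow(df)), function(k) {
    ring <- cell_polygon(grid, df$cell[k])
    props <- list(cell = df$cell[k], risk = df$risk[k])
    if (has_class) props$class <- df$class[k]
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = props
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Closed ring of a cell's corners in lon/lat (list of lon/lat pairs).
cell_polygon <- function(grid, id) {
  row <- (id - 1L) %/% grid$ncols
  col <- (id - 1L) %% grid$ncols
  cx <- grid$x0 + c(col, col + 1, col + 1, col, col) * grid$cell_size
  cy <- grid$y0 + c(row, row, row + 1, row + 1, row) * grid$cell_size
  ll <- laea_unproject(cx, cy, grid$lon0, grid$lat0)
  purrr::map(seq_along(ll$lon), function(k) c(ll$lon[k], ll$lat[k]))
}

#' Read back an exported origin-risk CSV
#'
#' @param path CSV written by [export_risk_map()].
#' @return A tibble with the exported columns; `cell` and `risk` reproduce
#'   the exported map exactly.
#' @export
read_risk_map <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    cell = readr::col_integer(),
                    lon = readr::col_double(),
                    lat = readr::col_double(),
                    risk = readr::col_double(),
                    .default = readr::col_character()
                  ))
}
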