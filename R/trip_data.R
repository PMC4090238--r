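# Trip records and preprocessing: seasonal filtering, grid aggregation,
# low-frequency filtering, and return-segment augmentation.

#' Read origin-destination trip records
#'
#' Reads a delimited file of camper reservation records, one row per
#' reservation: origin point, destination point, visit date, and the number
#' of trips the row represents (defaults to 1 when the column is absent).
#'
#' @param path Path to a CSV/TSV file.
#' @param columns Named character vector mapping the roles
#'   `origin_lon`, `origin_lat`, `dest_lon`, `dest_lat`, `date` and
#'   (optionally) `count` to column names in the file.
#' @param delim Field delimiter; default `","`.
#' @return A tibble with columns `origin_lon`, `origin_lat`, `dest_lon`,
#'   `dest_lat`, `visit_date` (Date) and `count` (integer), in file order.
#'   Malformed coordinates or dates raise an error naming the offending data
#'   row; an empty file yields an empty tibble.
#' @export
read_trips <- function(path,
                       columns = c(
                         origin_lon = "origin_lon", origin_lat = "origin_lat",
                         dest_lon = "dest_lon", dest_lat = "dest_lat",
                         date = "visit_date", count = "count"
                       ),
                       delim = ",") {
  if (!file.exists(path)) stop("trip file not found: ", path, call. = FALSE)
  empty <- tibble::tibble(
    origin_lon = double(), origin_lat = double(),
    dest_lon = double(), dest_lat = double(),
    visit_date = as.Date(character()), count = integer()
  )
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(empty)

  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0L) return(empty)

  need <- c("origin_lon", "origin_lat", "dest_lon", "dest_lat", "date")
  missing_roles <- setdiff(need, names(columns))
  if (length(missing_roles) > 0) {
    stop("`columns` must map roles: ", paste(missing_roles, collapse = ", "),
         call. = FALSE)
  }
  for (role in need) {
    if (!columns[[role]] %in% names(raw)) {
      stop("column '", columns[[role]], "' (", role, ") not found in ", path,
           call. = FALSE)
    }
  }

  num_col <- function(role, lo, hi, what) {
    v <- suppressWarnings(as.numeric(raw[[columns[[role]]]]))
    bad <- which(!is.finite(v) | v < lo | v > hi)
    if (length(bad) > 0) {
      stop("malformed ", what, " in row ", bad[1],
           " (value '", raw[[columns[[role]]]][bad[1]], "')", call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    origin_lon = num_col("origin_lon", -180, 180, "origin longitude"),
    origin_lat = num_col("origin_lat", -90, 90, "origin latitude"),
    dest_lon = num_col("dest_lon", -180, 180, "destination longitude"),
    dest_lat = num_col("dest_lat", -90, 90, "destination latitude")
  )
  dates <- suppressWarnings(as.Date(raw[[columns[["date"]]]], format = "%Y-%m-%d"))
  bad <- which(is.na(dates))
  if (length(bad) > 0) {
    stop("malformed date in row ", bad[1],
         " (value '", raw[[columns[["date"]]]][bad[1]], "'; expected ISO-8601)",
         call. = FALSE)
  }
  out$visit_date <- dates

  if (!is.na(columns["count"]) && columns[["count"]] %in% names(raw)) {
    cnt <- suppressWarnings(as.numeric(raw[[columns[["count"]]]]))
    cnt[is.na(raw[[columns[["count"]]]])] <- 1
    bad <- which(!is.finite(cnt) | cnt < 1 | cnt != round(cnt))
    if (length(bad) > 0) {
      stop("malformed trip count in row ", bad[1],
           " (value '", raw[[columns[["count"]]]][bad[1]], "')", call. = FALSE)
    }
    out$count <- as.integer(cnt)
  } else {
    out$count <- 1L
  }
  out
}

#' Seasonal window of peak borer emergence
#'
#' Defines the late spring-early summer window used to filter reservations:
#' a start date (month-day, applied in the year of each visit) plus a window
#' length in weeks, default 10. A per-location hook accommodates
#' geographically varying season starts: `start_fun(lon, lat)` must return
#' `"MM-DD"` strings for arbitrary points.
#'
#' @param start Window start as `"MM-DD"` (default `"05-01"`).
#' @param weeks Window length in weeks (> 0), default 10.
#' @param start_fun Optional vectorised function `(lon, lat) -> "MM-DD"`
#'   giving a location-specific start; overrides `start`.
#' @return An object of class `season_model`.
#' @export
season_model <- function(start = "05-01", weeks = 10, start_fun = NULL) {
  if (!is.numeric(weeks) || length(weeks) != 1L || weeks <= 0) {
    stop("`weeks` must be a single positive number", call. = FALSE)
  }
  if (is.null(start_fun)) {
    if (is.na(as.Date(paste0("2001-", start), format = "%Y-%m-%d"))) {
      stop("`start` must be a valid 'MM-DD' month-day", call. = FALSE)
    }
  } else if (!is.function(start_fun)) {
    stop("`start_fun` must be a function (lon, lat) -> 'MM-DD'", call. = FALSE)
  }
  structure(list(start = start, weeks = weeks, start_fun = start_fun),
            class = "season_model")
}

# Window membership: inclusive start, exclusive end (start + weeks*7 days),
# anchored in each visit's own year.
season_contains <- function(season, lon, lat, date) {
  md <- if (is.null(season$start_fun)) {
    rep(season$start, length(date))
  } else {
    season$start_fun(lon, lat)
  }
  start <- as.Date(paste0(format(date, "%Y"), "-", md), format = "%Y-%m-%d")
  if (anyNA(start)) {
    stop("season start function returned an invalid 'MM-DD' value", call. = FALSE)
  }
  date >= start & date < start + season$weeks * 7
}

#' Filter trips to the seasonal emergence window
#'
#' Retains exactly those trips whose visit date falls inside the seasonal
#' window at **both** the origin and the destination location, preserving row
#' order. Trips during the window at only one endpoint are removed, since a
#' successful transfer needs emergence-ready insects at the source and a
#' receptive season at the destination.
#'
#' @param trips A trip tibble as returned by [read_trips()].
#' @param season A [season_model()].
#' @return The filtered trip tibble.
#' @export
filter_season <- function(trips, season) {
  stopifnot(inherits(season, "season_model"))
  if (nrow(trips) == 0L) return(trips)
  keep <- season_contains(season, trips$origin_lon, trips$origin_lat, trips$visit_date) &
    season_contains(season, trips$dest_lon, trips$dest_lat, trips$visit_date)
  trips[keep, , drop = FALSE]
}

# ---- segment tables ---------------------------------------------------------

new_segment_table <- function(df, period = NA_character_) {
  df <- tibble::tibble(
    cell_i = as.integer(df$cell_i),
    cell_j = as.integer(df$cell_j),
    weight = as.numeric(df$weight)
  )
  structure(df, period = period,
            class = c("segment_table", class(tibble::tibble())))
}

#' Build a segment table by hand
#'
#' A segment table holds the sparse travel-frequency matrix: one row per
#' ordered cell pair (i, j), i != j, with positive weight `m_ij`.
#'
#' @param cell_i,cell_j Integer cell ids (no diagonal pairs).
#' @param weight Positive trip weights `m_ij` (fractional allowed once return
#'   segments are added).
#' @param period Optional label for the study period `t`.
#' @return A `segment_table` tibble with columns `cell_i`, `cell_j`, `weight`.
#' @export
segment_table <- function(cell_i = integer(), cell_j = integer(),
                          weight = numeric(), period = NA_character_) {
  stopifnot(length(cell_i) == length(cell_j), length(cell_i) == length(weight))
  if (any(cell_i == cell_j)) {
    stop("segment table cannot hold diagonal (i = j) entries", call. = FALSE)
  }
  if (any(!is.finite(weight) | weight <= 0)) {
    stop("segment weights must be positive and finite", call. = FALSE)
  }
  dup <- duplicated(paste(cell_i, cell_j))
  if (any(dup)) stop("duplicate (i, j) pairs in segment table", call. = FALSE)
  new_segment_table(
    tibble::tibble(cell_i = cell_i, cell_j = cell_j, weight = weight),
    period = period
  )
}

#' @export
print.segment_table <- function(x, ...) {
  n_nodes <- length(unique(c(x$cell_i, x$cell_j)))
  cat(sprintf("<segment_table> %d segments over %d cells (period: %s)\n",
              nrow(x), n_nodes, attr(x, "period")))
  NextMethod()
}

#' Aggregate trips onto the analysis grid
#'
#' Maps each trip's origin and destination point to a grid cell and sums trip
#' counts per ordered cell pair, giving the travel-frequency entries `m_ij`.
#' Trips whose origin and destination fall in the same cell are discarded:
#' the diagonal of the travel matrix is fixed at zero, since within-cell
#' movement carries no between-node dispersal.
#'
#' @param trips A trip tibble.
#' @param grid A [grid_spec()]; all trip points must fall inside its extent.
#' @param period Optional period label stored on the result.
#' @return A `segment_table`.
#' @export
aggregate_to_grid <- function(trips, grid, period = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(trips) == 0L) return(segment_table(period = period))
  ci <- tryCatch(
    cell_of(grid, trips$origin_lon, trips$origin_lat),
    error = function(e) stop("trip origin ", conditionMessage(e), call. = FALSE)
  )
  cj <- tryCatch(
    cell_of(grid, trips$dest_lon, trips$dest_lat),
    error = function(e) stop("trip destination ", conditionMessage(e), call. = FALSE)
  )
  keep <- ci != cj
  agg <- tibble::tibble(cell_i = ci[keep], cell_j = cj[keep],
                        weight = as.numeric(trips$count[keep])) |>
    dplyr::group_by(.data$cell_i, .data$cell_j) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$cell_i, .data$cell_j)
  new_segment_table(agg, period = period)
}

#' Drop low-frequency segments
#'
#' Removes cell pairs with fewer than `min_trips` trips. The default of 4
#' implements the rule that pairs with three or fewer trips over the study
#' period are dropped; the operation is idempotent.
#'
#' @param segments A `segment_table`.
#' @param min_trips Minimum weight retained (>= 1). Default 4.
#' @return The filtered `segment_table`.
#' @export
filter_low_frequency <- function(segments, min_trips = 4) {
  stopifnot(inherits(segments, "segment_table"))
  if (!is.numeric(min_trips) || length(min_trips) != 1L || min_trips < 1) {
    stop("`min_trips` must be a single number >= 1", call. = FALSE)
  }
  new_segment_table(segments[segments$weight >= min_trips, , drop = FALSE],
                    period = attr(segments, "period"))
}

# Same rule applied at raw point-pair resolution, before aggregation.
filter_low_frequency_trips <- function(trips, min_trips = 4) {
  if (!is.numeric(min_trips) || length(min_trips) != 1L || min_trips < 1) {
    stop("`min_trips` must be a single number >= 1", call. = FALSE)
  }
  if (nrow(trips) == 0L) return(trips)
  key <- paste(trips$origin_lon, trips$origin_lat,
               trips$dest_lon, trips$dest_lat, sep = "|")
  tot <- tapply(trips$count, key, sum)
  trips[tot[key] >= min_trips, , drop = FALSE]
}

#' Add return segments for unburned firewood
#'
#' For every forward segment (i, j) with weight `m_ij`, increments the
#' reverse segment (j, i) by `return_fraction * m_ij` on top of any observed
#' reverse travel. The default 0.15 reflects survey evidence that about 15%
#' of firewood-carrying campers bring unused firewood home. Increments are
#' computed from the input weights only (no cascading), and reverse weights
#' stay fractional: they feed probabilities, not counts.
#'
#' @param segments A `segment_table`.
#' @param return_fraction Fraction in \[0, 1\]; default 0.15.
#' @return A `segment_table` including the return segments.
#' @export
add_return_segments <- function(segments, return_fraction = 0.15) {
  stopifnot(inherits(segments, "segment_table"))
  if (!is.numeric(return_fraction) || length(return_fraction) != 1L ||
      return_fraction < 0 || return_fraction > 1) {
    stop("`return_fraction` must be a single number in [0, 1]", call. = FALSE)
  }
  if (return_fraction == 0 || nrow(segments) == 0L) return(segments)
  ret <- tibble::tibble(
    cell_i = segments$cell_j, cell_j = segments$cell_i,
    weight = return_fraction * segments$weight
  )
  out <- dplyr::bind_rows(tibble::as_tibble(segments)[c("cell_i", "cell_j", "weight")], ret) |>
    dplyr::group_by(.data$cell_i, .data$cell_j) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$cell_i, .data$cell_j)
  new_segment_table(out, period = attr(segments, "period"))
}

#' Run the full trip preprocessing pipeline
#'
#' Convenience wrapper chaining the preprocessing steps: seasonal filter,
#' low-frequency filter, grid aggregation, and return-segment augmentation.
#' By default the low-frequency rule is applied at raw origin-destination
#' point-pair resolution before aggregation (`filter_level = "pair"`, which
#' keeps the subsequent aggregation tractable on large files);
#' `filter_level = "cell"` applies it to aggregated cell pairs instead.
#'
#' @param trips A trip tibble from [read_trips()].
#' @param grid A [grid_spec()].
#' @param season A [season_model()], or `NULL` to skip seasonal filtering.
#' @param min_trips Low-frequency cutoff, see [filter_low_frequency()].
#' @param return_fraction See [add_return_segments()].
#' @param filter_level `"pair"` (raw point pairs, before aggregation) or
#'   `"cell"` (aggregated cell pairs).
#' @param period Optional period label.
#' @return A `segment_table` ready for [build_travel_matrix()].
#' @export
preprocess_trips <- function(trips, grid, season = season_model(),
                             min_trips = 4, return_fraction = 0.15,
                             filter_level = c("pair", "cell"),
                             period = NA_character_) {
  filter_level <- match.arg(filter_level)
  if (!is.null(season)) trips <- filter_season(trips, season)
  if (filter_level == "pair") {
    trips <- filter_low_frequency_trips(trips, min_trips)
    segs <- aggregate_to_grid(trips, grid, period = period)
  } else {
    segs <- aggregate_to_grid(trips, grid, period = period)
    segs <- filter_low_frequency(segs, min_trips)
  }
  add_return_segments(segs, return_fraction)
}

#' Read and write segment tables as sparse CSV
#'
#' Segment tables serialise as three-column CSV (`cell_i`, `cell_j`,
#' `weight`); values round-trip exactly.
#'
#' @param segments A `segment_table`.
#' @param path CSV file path.
#' @return `write_segments()` returns `path` invisibly; `read_segments()`
#'   returns a `segment_table`.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_table"))
  readr::write_csv(tibble::as_tibble(segments)[c("cell_i", "cell_j", "weight")], path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      cell_i = readr::col_integer(), cell_j = readr::col_integer(),
      weight = readr::col_double()
    ),
    progress = FALSE
  )
  segment_table(df$cell_i, df$cell_j, df$weight)
}
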