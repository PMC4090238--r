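# Synthetic trip-record generation: a landscape of clustered population
# centres and heavy-tailed campground popularities, a quantile-calibrated
# lognormal distance kernel, and small end-to-end fixture bundles.

default_extent <- function() {
  c(lon_min = -125, lon_max = -67, lat_min = 25, lat_max = 49)
}

#' Generate a synthetic landscape of origins and campgrounds
#'
#' Population centres (trip-generating origin locations) are placed by a
#' clustered (Thomas-like) point process — uniform parent points with
#' Gaussian offspring — with lognormal trip-generation weights. Campgrounds
#' are placed uniformly with heavy-tailed lognormal popularity weights, so a
#' small number of highly popular destinations dominate visitation, as in
#' real reservation data.
#'
#' @param n_centers Number of population centres (>= 1). Default 400.
#' @param n_campgrounds Number of campgrounds (>= 1). Default 200.
#' @param extent Named lon/lat extent; defaults to the contiguous-US scale.
#' @param seed Integer seed; the landscape is deterministic given the seed.
#' @return A `synthetic_landscape`: list with tibbles `centers`
#'   (`lon`, `lat`, `weight`) and `campgrounds` (`lon`, `lat`, `popularity`),
#'   plus `extent`.
#' @export
generate_landscape <- function(n_centers = 400, n_campgrounds = 200,
                               extent = default_extent(), seed = 1L) {
  if (!is.numeric(n_centers) || n_centers < 1 ||
      !is.numeric(n_campgrounds) || n_campgrounds < 1) {
    stop("`n_centers` and `n_campgrounds` must be >= 1", call. = FALSE)
  }
  extent <- as.list(extent)
  withr::with_seed(as.integer(seed), {
    n_parents <- max(1L, as.integer(ceiling(n_centers / 8)))
    par_lon <- stats::runif(n_parents, extent$lon_min, extent$lon_max)
    par_lat <- stats::runif(n_parents, extent$lat_min, extent$lat_max)
    pick <- sample.int(n_parents, n_centers, replace = TRUE)
    # ~80 km cluster spread, expressed in degrees
    sd_lat <- 80 / 111
    lat <- clamp(par_lat[pick] + stats::rnorm(n_centers, 0, sd_lat),
                 extent$lat_min, extent$lat_max)
    sd_lon <- sd_lat / cos(pmin(abs(lat), 80) * pi / 180)
    lon <- clamp(par_lon[pick] + stats::rnorm(n_centers, 0, sd_lon),
                 extent$lon_min, extent$lon_max)
    centers <- tibble::tibble(
      lon = lon, lat = lat,
      weight = stats::rlnorm(n_centers, meanlog = 0, sdlog = 1.2)
    )
    # Campgrounds are a mixture: most sit within reach of population
    # clusters (campers mostly live near the facilities they book), the
    # rest are remote destinations placed uniformly.
    n_near <- round(0.65 * n_campgrounds)
    # round-robin over parents so every population cluster has local options
    cg_pick <- if (n_near > 0) rep_len(sample.int(n_parents), n_near) else integer()
    cg_sd_lat <- 50 / 111
    cg_lat_near <- clamp(par_lat[cg_pick] + stats::rnorm(n_near, 0, cg_sd_lat),
                         extent$lat_min, extent$lat_max)
    cg_sd_lon <- cg_sd_lat / cos(pmin(abs(cg_lat_near), 80) * pi / 180)
    cg_lon_near <- clamp(par_lon[cg_pick] + stats::rnorm(n_near, 0, cg_sd_lon),
                         extent$lon_min, extent$lon_max)
    n_far <- n_campgrounds - n_near
    campgrounds <- tibble::tibble(
      lon = c(cg_lon_near, stats::runif(n_far, extent$lon_min, extent$lon_max)),
      lat = c(cg_lat_near, stats::runif(n_far, extent$lat_min, extent$lat_max)),
      popularity = stats::rlnorm(n_campgrounds, meanlog = 0, sdlog = 1.5)
    )
    structure(
      list(centers = centers, campgrounds = campgrounds, extent = extent),
      class = "synthetic_landscape"
    )
  })
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("<synthetic_landscape> %d population centers, %d campgrounds\n",
              nrow(x$centers), nrow(x$campgrounds)))
  invisible(x)
}

#' Lognormal trip-distance kernel
#'
#' The one-way trip-distance kernel, lognormal by default. The default
#' parameters are the closed-form solution of the two quantile constraints
#' observed in reservation data — half of trips within 100 km and a tenth
#' beyond 500 km: `meanlog = log(100)`, `sdlog = log(5) / qnorm(0.9)`.
#'
#' @param meanlog,sdlog Lognormal parameters (distance in km).
#' @return An object of class `distance_kernel` with a `density` function.
#' @seealso [calibrate_kernel()] to adjust the parameters so that a given
#'   landscape's marginal trip-distance distribution meets the constraints.
#' @export
distance_kernel <- function(meanlog = log(100),
                            sdlog = log(5) / stats::qnorm(0.9)) {
  if (!is.finite(meanlog) || !is.finite(sdlog) || sdlog <= 0) {
    stop("kernel parameters must be finite with sdlog > 0", call. = FALSE)
  }
  structure(
    list(
      family = "lognormal", meanlog = meanlog, sdlog = sdlog,
      density = function(d) stats::dlnorm(d, meanlog = meanlog, sdlog = sdlog)
    ),
    class = "distance_kernel"
  )
}

#' @export
print.distance_kernel <- function(x, ...) {
  cat(sprintf("<distance_kernel> %s(meanlog = %.4f, sdlog = %.4f)\n",
              x$family, x$meanlog, x$sdlog))
  invisible(x)
}

# Destination-choice weights, one row per centre, rows summing to 1.
# Computed in log space (log kernel density + log popularity, shifted by
# the row maximum) so extreme calibrated parameters — e.g. the large-sdlog
# power-law-like limit — stay numerically stable.
destination_weights <- function(dist_km, popularity, meanlog, sdlog) {
  logw <- stats::dlnorm(dist_km, meanlog = meanlog, sdlog = sdlog, log = TRUE)
  logw <- sweep(logw, 2, log(popularity), `+`)
  w <- exp(logw - apply(logw, 1, max))
  w / rowSums(w)
}

# Exact marginal trip-distance CDF mass below each cutoff, for a landscape
# and kernel: destination choice is popularity x kernel(distance), so the
# marginal is a center-weighted mixture over the discrete campground set,
# computable in closed form from the distance matrix.
marginal_distance_mass <- function(dist_km, center_w, popularity,
                                   meanlog, sdlog, cutoffs) {
  w <- destination_weights(dist_km, popularity, meanlog, sdlog)
  cw <- center_w / sum(center_w)
  vapply(cutoffs, function(x) sum(cw * rowSums(w * (dist_km <= x))),
         numeric(1))
}

#' Calibrate the distance kernel to a landscape
#'
#' Destination choice is proportional to popularity times kernel density, so
#' the realised (marginal) trip-distance distribution over a discrete
#' campground set is tilted away from the kernel itself by the landscape's
#' geometry. This solves numerically for the lognormal parameters such that
#' the marginal distribution meets the two quantile constraints —
#' `P(D <= q_near) = p_near` and `P(D > q_far) = p_far` — before any
#' sampling. The calibration is deterministic: the marginal is computed in
#' closed form from the centre-campground great-circle distance matrix.
#'
#' @param landscape A [generate_landscape()] result.
#' @param q_near,p_near Near-distance constraint; default `P(D <= 100) = 0.5`.
#' @param q_far,p_far Far-tail constraint; default `P(D > 500) = 0.1`.
#' @return A calibrated [distance_kernel()].
#' @export
calibrate_kernel <- function(landscape, q_near = 100, p_near = 0.5,
                             q_far = 500, p_far = 0.1) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  dist_km <- geosphere::distm(
    as.matrix(landscape$centers[, c("lon", "lat")]),
    as.matrix(landscape$campgrounds[, c("lon", "lat")]),
    fun = geosphere::distHaversine
  ) / 1000
  mass <- function(meanlog, sdlog) {
    marginal_distance_mass(
      dist_km, landscape$centers$weight, landscape$campgrounds$popularity,
      meanlog, sdlog, c(q_near, q_far)
    )
  }
  # Profile solve: near-mass is monotone decreasing in meanlog, so for each
  # sdlog solve the near constraint by root finding, then pick the sdlog
  # whose far tail is closest to p_far.
  mu_rng <- c(log(1e-4), log(5000))
  solve_mu <- function(sdlog) {
    g <- function(mu) mass(mu, sdlog)[1] - p_near
    lo <- g(mu_rng[1]); hi <- g(mu_rng[2])
    if (is.na(lo) || is.na(hi) || lo * hi > 0) return(NA_real_)
    stats::uniroot(g, mu_rng, tol = 1e-8)$root
  }
  tail_err <- function(sdlog) {
    mu <- solve_mu(sdlog)
    if (is.na(mu)) return(10)
    abs((1 - mass(mu, sdlog)[2]) - p_far)
  }
  sd_grid <- seq(0.4, 3.2, by = 0.1)
  errs <- vapply(sd_grid, tail_err, numeric(1))
  sd_prof <- sd_grid[which.min(errs)]
  mu_prof <- solve_mu(sd_prof)

  # Joint polish: both constraints weighted by their natural scales, so
  # when the landscape geometry cannot satisfy them exactly the solution
  # splits the residual proportionally instead of sacrificing the far tail.
  loss <- function(par) {
    m <- mass(par[1], exp(par[2]))
    ((m[1] - p_near) / 0.01)^2 + (((1 - m[2]) - p_far) / 0.006)^2
  }
  starts <- list(
    c(log(q_near), log(log(q_far / q_near) / stats::qnorm(1 - p_far)))
  )
  if (!is.na(mu_prof)) starts <- c(starts, list(c(mu_prof, log(sd_prof))))
  starts <- c(starts, list(c(-2, log(2))))
  fits <- lapply(starts, function(s) {
    stats::optim(s, loss, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-12))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  distance_kernel(meanlog = best$par[1], sdlog = exp(best$par[2]))
}

#' Generate synthetic trip records
#'
#' Draws trips from a landscape: an origin centre is chosen proportional to
#' its weight, then a destination campground proportional to popularity
#' times kernel density at the centre-campground great-circle distance.
#' Origin points are jittered a few km around their centre (emulating
#' distinct addresses within a community) and visit dates are uniform over
#' the supplied season. With `kernel = NULL` (default) the kernel is first
#' calibrated to the landscape with [calibrate_kernel()], so the marginal
#' trip-distance distribution has about half its mass within 100 km and a
#' tenth beyond 500 km.
#'
#' @param landscape A [generate_landscape()] result.
#' @param n_trips Number of trips (>= 0).
#' @param kernel A [distance_kernel()], or `NULL` to calibrate one.
#' @param season_start,season_end Date range (inclusive) for visit dates.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param jitter_km Gaussian origin jitter (sd, km). Default 5.
#' @return A trip tibble with the [read_trips()] columns.
#' @export
generate_trips <- function(landscape, n_trips, kernel = NULL,
                           season_start = as.Date("2008-05-01"),
                           season_end = as.Date("2008-07-09"),
                           seed = 1L, jitter_km = 5) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  if (!is.numeric(n_trips) || n_trips < 0) {
    stop("`n_trips` must be >= 0", call. = FALSE)
  }
  empty <- tibble::tibble(
    origin_lon = double(), origin_lat = double(),
    dest_lon = double(), dest_lat = double(),
    visit_date = as.Date(character()), count = integer()
  )
  if (n_trips == 0) return(empty)
  if (is.null(kernel)) kernel <- calibrate_kernel(landscape)
  stopifnot(inherits(kernel, "distance_kernel"))

  ctr <- landscape$centers
  cg <- landscape$campgrounds
  dist_km <- geosphere::distm(
    as.matrix(ctr[, c("lon", "lat")]), as.matrix(cg[, c("lon", "lat")]),
    fun = geosphere::distHaversine
  ) / 1000
  dest_w <- destination_weights(dist_km, cg$popularity, kernel$meanlog,
                                kernel$sdlog)

  withr::with_seed(as.integer(seed), {
    origin_idx <- sample.int(nrow(ctr), n_trips, replace = TRUE,
                             prob = ctr$weight)
    dest_idx <- integer(n_trips)
    for (c_idx in unique(origin_idx)) {
      rows <- which(origin_idx == c_idx)
      w <- dest_w[c_idx, ]
      if (sum(w) <= 0) w <- cg$popularity
      dest_idx[rows] <- sample.int(nrow(cg), length(rows), replace = TRUE,
                                   prob = w)
    }
    sd_lat <- jitter_km / 111
    olat <- clamp(ctr$lat[origin_idx] + stats::rnorm(n_trips, 0, sd_lat),
                  landscape$extent$lat_min, landscape$extent$lat_max)
    sd_lon <- sd_lat / cos(pmin(abs(olat), 80) * pi / 180)
    olon <- clamp(ctr$lon[origin_idx] + stats::rnorm(n_trips, 0, sd_lon),
                  landscape$extent$lon_min, landscape$extent$lon_max)
    dates <- season_start +
      sample.int(as.integer(season_end - season_start) + 1L, n_trips,
                 replace = TRUE) - 1L
    tibble::tibble(
      origin_lon = olon, origin_lat = olat,
      dest_lon = cg$lon[dest_idx], dest_lat = cg$lat[dest_idx],
      visit_date = dates, count = 1L
    )
  })
}

#' One-way great-circle trip distances
#'
#' @param trips A trip tibble.
#' @return Numeric vector of origin-destination distances in km.
#' @export
trip_distances <- function(trips) {
  if (nrow(trips) == 0L) return(numeric(0))
  geosphere::distHaversine(
    as.matrix(trips[, c("origin_lon", "origin_lat")]),
    as.matrix(trips[, c("dest_lon", "dest_lat")])
  ) / 1000
}

# ---- fixture scenarios ------------------------------------------------------

fixture_geometry <- function() {
  extent <- c(lon_min = -100, lon_max = -92, lat_min = 38, lat_max = 44)
  list(
    extent = extent,
    # target "state": the eastern strip; its boundary polygon
    target_poly = cbind(
      lon = c(-94.5, -92, -92, -94.5, -94.5),
      lat = c(38, 38, 44, 44, 38)
    ),
    # region lon breaks used to label origin cells in assertions
    adjacent_lon = c(-97.8, -94.5),
    distant_lon = c(-100, -97.8)
  )
}

fixture_points <- function(scenario) {
  geom <- fixture_geometry()
  grid_pts <- function(lon_rng, lat_rng, n_lon, n_lat) {
    expand.grid(
      lon = seq(lon_rng[1], lon_rng[2], length.out = n_lon),
      lat = seq(lat_rng[1], lat_rng[2], length.out = n_lat)
    )
  }
  adjacent <- grid_pts(c(-97.3, -94.8), c(38.5, 43.5), 6, 4)   # 24 pts
  far <- grid_pts(c(-99.8, -98.2), c(39.5, 42.5), 3, 2)        # 6 pts
  hub <- grid_pts(c(-99.6, -99.4), c(42.8, 43.2), 2, 2)        # 4 pts, tight
  campgrounds <- grid_pts(c(-94.2, -92.3), c(39.5, 42.5), 4, 2) # 8 pts in target

  weights <- switch(
    scenario,
    two_state_local = rbind(
      cbind(adjacent, weight = 0.90 / nrow(adjacent)),
      cbind(far, weight = 0.10 / nrow(far))
    ),
    hub_and_spoke_distant = rbind(
      cbind(adjacent[seq(1, 24, by = 2), ], weight = 0.30 / 12),
      cbind(hub, weight = 0.70 / nrow(hub))
    ),
    mixed = rbind(
      cbind(adjacent, weight = 0.55 / nrow(adjacent)),
      cbind(hub, weight = 0.35 / nrow(hub)),
      cbind(far, weight = 0.10 / nrow(far))
    ),
    stop("unknown scenario '", scenario, "'; expected one of ",
         "two_state_local, hub_and_spoke_distant, mixed", call. = FALSE)
  )
  list(geom = geom, origins = tibble::as_tibble(weights),
       campgrounds = tibble::tibble(
         lon = campgrounds$lon, lat = campgrounds$lat, popularity = 1
       ))
}

#' Build a self-contained test fixture bundle
#'
#' Emits a small synthetic bundle — trips CSV, grid JSON, jurisdiction cell
#' list, and scenario metadata — reproducing the two qualitative origin-risk
#' archetypes seen in state-level maps: `two_state_local` concentrates
#' origin risk in cells adjacent to the target region, while
#' `hub_and_spoke_distant` places the dominant origins in a distant hub
#' cluster; `mixed` combines both. Bundles are byte-identical given the same
#' seed.
#'
#' @param scenario One of `"two_state_local"`, `"hub_and_spoke_distant"`,
#'   `"mixed"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param n_trips Number of trip records; default 6000.
#' @return Invisibly, a list with the written `paths` and the in-memory
#'   objects: `trips`, `grid`, `jurisdiction`, and `regions` (a tibble
#'   labelling every origin cell as `adjacent` or `distant`).
#' @export
make_fixture <- function(scenario, seed = 1L, dir = tempfile("fixture"),
                         n_trips = 6000) {
  fx <- fixture_points(scenario)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  trips <- withr::with_seed(as.integer(seed), {
    oi <- sample.int(nrow(fx$origins), n_trips, replace = TRUE,
                     prob = fx$origins$weight)
    di <- sample.int(nrow(fx$campgrounds), n_trips, replace = TRUE,
                     prob = fx$campgrounds$popularity)
    dates <- as.Date("2008-05-01") + sample.int(70L, n_trips, replace = TRUE) - 1L
    tibble::tibble(
      origin_lon = fx$origins$lon[oi], origin_lat = fx$origins$lat[oi],
      dest_lon = fx$campgrounds$lon[di], dest_lat = fx$campgrounds$lat[di],
      visit_date = dates, count = 1L
    )
  })

  grid <- grid_spec(fx$geom$extent, cell_size = 15)
  jur <- jurisdiction("target_state", polygon = fx$geom$target_poly,
                      grid = grid)

  origin_cells <- unique(cell_of(grid, fx$origins$lon, fx$origins$lat))
  ctr <- cell_center(grid, origin_cells)
  regions <- tibble::tibble(
    cell = origin_cells,
    region = ifelse(ctr$lon >= fx$geom$adjacent_lon[1], "adjacent", "distant")
  )

  paths <- list(
    trips = file.path(dir, "trips.csv"),
    grid = file.path(dir, "grid.json"),
    jurisdiction = file.path(dir, "jurisdiction.csv"),
    meta = file.path(dir, "scenario.json")
  )
  readr::write_csv(trips, paths$trips)
  write_grid_spec(grid, paths$grid)
  readr::write_csv(
    tibble::tibble(name = jur$name, cell = jur$cells), paths$jurisdiction
  )
  jsonlite::write_json(
    list(scenario = scenario, seed = as.integer(seed), n_trips = n_trips,
         adjacent_lon_min = fx$geom$adjacent_lon[1]),
    paths$meta, auto_unbox = TRUE, digits = NA
  )
  invisible(list(paths = paths, trips = trips, grid = grid,
                 jurisdiction = jur, regions = regions))
}
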