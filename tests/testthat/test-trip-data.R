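header <- "origin_lon,origin_lat,dest_lon,dest_lat,visit_date,count"

test_that("read_trips parses rows, defaults counts, and preserves order", {
  path <- write_trip_csv(c(
    header,
    "-98.0,40.0,-93.0,41.0,2008-06-01,2",
    "-97.0,39.0,-94.0,42.0,2008-06-03,"
  ))
  trips <- read_trips(path)
  expect_equal(nrow(trips), 2L)
  expect_equal(trips$count, c(2L, 1L))
  expect_s3_class(trips$visit_date, "Date")
  expect_equal(trips$origin_lon, c(-98, -97))

  # count column absent entirely -> all counts default to 1
  path2 <- write_trip_csv(c(
    "origin_lon,origin_lat,dest_lon,dest_lat,visit_date",
    "-98.0,40.0,-93.0,41.0,2008-06-01"
  ))
  expect_equal(read_trips(path2)$count, 1L)
})

test_that("read_trips returns an empty collection for empty input", {
  expect_equal(nrow(read_trips(write_trip_csv(header))), 0L)
  expect_equal(nrow(read_trips(write_trip_csv(character()))), 0L)
})

test_that("read_trips names the offending row on malformed input", {
  path <- write_trip_csv(c(
    header,
    "-98.0,40.0,-93.0,41.0,2008-06-01,1",
    "-97.0,39.0,-94.0,42.0,2008-06-02,1",
    "-96.0,38.5,-94.5,42.0,2008-06-03,1",
    "-95.0,999,-94.0,41.0,2008-06-04,1"
  ))
  expect_error(read_trips(path), "row 4")
  path2 <- write_trip_csv(c(header, "-98.0,40.0,-93.0,41.0,junk,1"))
  expect_error(read_trips(path2), "row 1.*ISO-8601")
})

test_that("seasonal filter keeps trips inside both endpoint windows", {
  mk <- function(dates, olat = 40, dlat = 41) tibble::tibble(
    origin_lon = -98, origin_lat = olat, dest_lon = -93, dest_lat = dlat,
    visit_date = as.Date(dates), count = 1L
  )
  s <- season_model(start = "05-01", weeks = 10)
  # half-open window: May 1 (day 0) in, July 10 (day 70) out — brute-force
  # day count: as.Date("2008-07-10") - as.Date("2008-05-01") is 70 days
  expect_equal(as.integer(as.Date("2008-07-10") - as.Date("2008-05-01")), 70L)
  trips <- mk(c("2008-05-01", "2008-07-09", "2008-07-10", "2008-04-30"))
  kept <- filter_season(trips, s)
  expect_equal(kept$visit_date, as.Date(c("2008-05-01", "2008-07-09")))

  # a later window at the destination excludes a trip that is inside the
  # origin window only
  s2 <- season_model(start_fun = function(lon, lat) {
    ifelse(lat > 40.5, "06-01", "05-01")
  }, weeks = 10)
  trips2 <- mk("2008-05-15")            # origin window open, dest opens June 1
  expect_equal(nrow(filter_season(trips2, s2)), 0L)
  trips3 <- mk("2008-06-15")            # inside both
  expect_equal(nrow(filter_season(trips3, s2)), 1L)
})

test_that("aggregation sums counts per cell pair and drops same-cell trips", {
  g <- test_grid(cell_size = 100)
  # two distant locations (clearly different 100 km cells) and one same-cell
  # pair: expect a single entry of weight 3 (2 + 1 from counts)
  trips <- tibble::tibble(
    origin_lon = c(-99, -99.05, -93.0),
    origin_lat = c(38.5, 38.55, 43.5),
    dest_lon = c(-93, -93.05, -93.02),
    dest_lat = c(43.5, 43.55, 43.52),
    visit_date = as.Date("2008-06-01"), count = c(2L, 1L, 5L)
  )
  segs <- aggregate_to_grid(trips, g)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$weight, 3)
  expect_equal(segs$cell_i, cell_of(g, -99, 38.5))
  expect_equal(segs$cell_j, cell_of(g, -93, 43.5))

  expect_equal(nrow(aggregate_to_grid(trips[0, ], g)), 0L)
  out <- trips; out$dest_lon[1] <- -50
  expect_error(aggregate_to_grid(out, g), "destination")
})

test_that("aggregation conserves counts and ignores record order", {
  g <- test_grid()
  withr::with_seed(9, {
    n <- 300
    trips <- tibble::tibble(
      origin_lon = runif(n, -99.9, -92.1), origin_lat = runif(n, 38.1, 43.9),
      dest_lon = runif(n, -99.9, -92.1), dest_lat = runif(n, 38.1, 43.9),
      visit_date = as.Date("2008-06-01"),
      count = sample(1:3, n, replace = TRUE)
    )
  })
  segs <- aggregate_to_grid(trips, g)
  same_cell <- cell_of(g, trips$origin_lon, trips$origin_lat) ==
    cell_of(g, trips$dest_lon, trips$dest_lat)
  expect_equal(sum(segs$weight), sum(trips$count[!same_cell]))
  perm <- withr::with_seed(10, sample(nrow(trips)))
  segs2 <- aggregate_to_grid(trips[perm, ], g)
  expect_equal(as.data.frame(segs2), as.data.frame(segs))
})

test_that("low-frequency filter boundary sits between three and four trips", {
  segs <- segment_table(c(1L, 1L, 2L, 3L), c(2L, 3L, 3L, 1L), c(1, 3, 4, 5))
  kept <- filter_low_frequency(segs)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$weight >= 4))
  expect_false(any(kept$weight == 3))
  # idempotent, empty-safe, validated
  expect_equal(as.data.frame(filter_low_frequency(kept)), as.data.frame(kept))
  expect_equal(nrow(filter_low_frequency(segment_table())), 0L)
  expect_error(filter_low_frequency(segs, min_trips = 0), ">= 1")
})

test_that("return segments add the configured fraction of forward trips", {
  segs <- segment_table(1L, 2L, 100)
  out <- add_return_segments(segs)
  expect_equal(out$weight[out$cell_i == 2 & out$cell_j == 1], 15)
  expect_equal(out$weight[out$cell_i == 1 & out$cell_j == 2], 100)

  # observed reverse travel is incremented, not replaced, and increments
  # come from input weights only (both directions by hand):
  # m_12 = 100 -> adds 15 to (2,1); m_21 = 20 -> adds 3 to (1,2)
  both <- segment_table(c(1L, 2L), c(2L, 1L), c(100, 20))
  out2 <- add_return_segments(both)
  expect_equal(out2$weight[out2$cell_i == 2 & out2$cell_j == 1], 35)
  expect_equal(out2$weight[out2$cell_i == 1 & out2$cell_j == 2], 103)

  # identity at zero, validation outside [0, 1]
  expect_equal(as.data.frame(add_return_segments(segs, 0)), as.data.frame(segs))
  expect_error(add_return_segments(segs, 1.2), "\\[0, 1\\]")
})

test_that("return augmentation scales totals by (1 + f) without reverse trips", {
  for (seed in 1:3) {
    segs <- withr::with_seed(seed, {
      # upper-triangular pairs only, so no observed reverse entries
      i <- sample(1:10, 20, replace = TRUE)
      j <- sample(11:20, 20, replace = TRUE)
      k <- !duplicated(paste(i, j))
      segment_table(i[k], j[k], runif(sum(k), 1, 50))
    })
    f <- 0.15
    expect_equal(sum(add_return_segments(segs, f)$weight),
                 (1 + f) * sum(segs$weight))
  }
})

test_that("segment tables round-trip through sparse CSV", {
  segs <- random_segment_table(12, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_segments(segs, path)
  back <- read_segments(path)
  expect_equal(as.data.frame(back), as.data.frame(segs))
})

test_that("preprocess pipeline composes the steps at either filter level", {
  fx <- make_fixture("two_state_local", seed = 2, n_trips = 1500)
  by_pair <- preprocess_trips(fx$trips, fx$grid, filter_level = "pair")
  by_cell <- preprocess_trips(fx$trips, fx$grid, filter_level = "cell")
  expect_s3_class(by_pair, "segment_table")
  expect_gt(nrow(by_pair), 0)
  # cell-level filtering pools point pairs, so it can only keep more trips
  expect_gte(sum(by_cell$weight), sum(by_pair$weight))
})
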