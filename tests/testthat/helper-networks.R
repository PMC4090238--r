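# Shared builders for synthetic networks and hand-made risk matrices.

# Random sparse directed network: each ordered pair kept with `density`
# probability, lognormal weights.
random_segment_table <- function(n, seed, density = 0.15) {
  withr::with_seed(seed, {
    pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
    pairs <- pairs[pairs$i != pairs$j, ]
    pairs <- pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
    if (nrow(pairs) == 0L) pairs <- data.frame(i = 1L, j = 2L)
    segment_table(as.integer(pairs$i), as.integer(pairs$j),
                  stats::rlnorm(nrow(pairs), meanlog = 3, sdlog = 1))
  })
}

# Risk matrix with known phi values, bypassing simulation (for the pathway
# summaries, which are pure matrix algebra on phi).
manual_risk_matrix <- function(cell_i, cell_j, phi, sims = 10000L) {
  hits <- as.integer(round(phi * sims))
  structure(
    tibble::tibble(cell_i = as.integer(cell_i), cell_j = as.integer(cell_j),
                   hits = hits, phi = phi),
    sims_per_origin = sims, seed = 0L,
    origins = unique(as.integer(cell_i)), cap_hits = 0L,
    class = c("risk_matrix", class(tibble::tibble()))
  )
}

# A small mid-latitude grid for geometry tests.
test_grid <- function(cell_size = 15) {
  grid_spec(c(lon_min = -100, lon_max = -92, lat_min = 38, lat_max = 44),
            cell_size = cell_size)
}

# Column content only: drops every attribute a pipeline may have attached.
df_plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  x
}

write_trip_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
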