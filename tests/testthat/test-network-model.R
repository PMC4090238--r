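test_that("travel matrix validation fixes the node set and rejects diagonals", {
  m <- build_travel_matrix(segment_table(c(1L, 5L), c(5L, 9L), c(100, 7)))
  expect_equal(attr(m, "nodes"), c(1L, 5L, 9L))
  expect_equal(nrow(build_travel_matrix(segment_table())), 0L)
  bad <- tibble::tibble(cell_i = c(1L, 2L), cell_j = c(1L, 3L), weight = c(5, 1))
  expect_error(build_travel_matrix(bad), "diagonal")
})

test_that("transition scaling matches closed-form arithmetic", {
  # single segment m = 100, safety 0.9: lambda = 0.009, p = 0.9, term = 0.1
  tm <- scale_to_transition(segment_table(1L, 2L, 100), safety = 0.9)
  expect_equal(tm$lambda, 0.009)
  expect_equal(tm$p$p_ij, 0.9)
  expect_equal(tm$p_term$p_term[tm$p_term$cell == 1], 0.1)
  # destination-only node is a pure sink
  expect_equal(tm$p_term$p_term[tm$p_term$cell == 2], 1)

  # two rows with sums 100 and 50: row-2 termination 1 - 0.9 * 50/100 = 0.55
  tm2 <- scale_to_transition(
    segment_table(c(1L, 1L, 2L), c(2L, 3L, 3L), c(60, 40, 50)), safety = 0.9
  )
  expect_equal(tm2$p_term$p_term[tm2$p_term$cell == 2], 0.55)
  expect_equal(tm2$p_term$p_term[tm2$p_term$cell == 1], 0.1)

  expect_error(scale_to_transition(segment_table()), "lambda")
  expect_error(scale_to_transition(segment_table(1L, 2L, 10), safety = 1), "0, 1")
})

test_that("every transition row conserves probability mass", {
  for (seed in 1:5) {
    tm <- scale_to_transition(random_segment_table(30, seed))
    out <- tapply(tm$p$p_ij, factor(tm$p$cell_i, levels = tm$nodes), sum,
                  default = 0)
    total <- as.numeric(out) + tm$p_term$p_term
    expect_true(all(abs(total - 1) < 1e-12))
    expect_true(all(as.numeric(out) < 1))
  }
})

test_that("single walks terminate correctly and replay under the same seed", {
  tm <- scale_to_transition(segment_table(1L, 2L, 100), safety = 0.9)
  # absorbing origin: a model where node 3 exists only as destination
  p <- simulate_path(tm, 2L, seed = 1)
  expect_equal(p$visited, integer(0))
  expect_equal(p$termination, "no_outgoing")

  chain <- scale_to_transition(
    segment_table(c(1L, 2L), c(2L, 3L), c(100, 100)), safety = 0.9
  )
  p1 <- simulate_path(chain, 1L, seed = 42)
  p2 <- simulate_path(chain, 1L, seed = 42)
  expect_identical(p1$visited, p2$visited)
  expect_identical(p1$termination, p2$termination)
  expect_error(simulate_path(chain, 99L, seed = 1), "not a node")
})

test_that("two-node visit frequency matches the transition probability", {
  tm <- scale_to_transition(segment_table(1L, 2L, 100), safety = 0.9)
  phi <- estimate_phi(tm, origins = 1L, sims_per_origin = 1e5, seed = 31)
  # binomial: se = sqrt(0.9 * 0.1 / 1e5) ~ 0.00095
  expect_lt(abs(phi$phi[phi$cell_j == 2] - 0.9), 4 * sqrt(0.9 * 0.1 / 1e5))
})

test_that("chain visit risk multiplies along links and stays in [0, 1]", {
  chain <- scale_to_transition(
    segment_table(c(1L, 2L), c(2L, 3L), c(100, 100)), safety = 0.5
  )
  phi <- estimate_phi(chain, origins = 1L, sims_per_origin = 1e5, seed = 8)
  est13 <- phi$phi[phi$cell_j == 3]
  expect_lt(abs(est13 - 0.25), 4 * sqrt(0.25 * 0.75 / 1e5))
  expect_true(all(phi$phi >= 0 & phi$phi <= 1))
  expect_equal(phi$phi, phi$hits / attr(phi, "sims_per_origin"))
})

test_that("an absorbing origin yields zero risk everywhere", {
  tm <- scale_to_transition(segment_table(1L, 2L, 100), safety = 0.9)
  phi <- estimate_phi(tm, origins = 2L, sims_per_origin = 1000, seed = 3)
  expect_equal(nrow(phi), 0L)
})

test_that("risk estimates are reproducible and origin-order invariant", {
  tm <- scale_to_transition(random_segment_table(15, seed = 21))
  origins <- tm$p_term$cell[tm$p_term$p_term < 1][1:4]
  a <- estimate_phi(tm, origins = origins, sims_per_origin = 2000, seed = 5)
  b <- estimate_phi(tm, origins = origins, sims_per_origin = 2000, seed = 5)
  expect_identical(df_plain(a), df_plain(b))
  c_ <- estimate_phi(tm, origins = rev(origins), sims_per_origin = 2000, seed = 5)
  expect_equal(
    df_plain(dplyr::arrange(tibble::as_tibble(c_), cell_i, cell_j)),
    df_plain(a)
  )
})

test_that("analytic visit probability reproduces closed-form cases", {
  chain <- scale_to_transition(
    segment_table(c(1L, 2L), c(2L, 3L), c(100, 100)), safety = 0.5
  )
  expect_equal(analytic_visit_probability(chain, 1L, 3L), 0.25)
  expect_equal(analytic_visit_probability(chain, 1L, 2L), 0.5)
  # no directed path
  expect_equal(analytic_visit_probability(chain, 3L, 1L), 0)
  # two-node cycle p = 0.5 each way: h(1 -> 2) = 0.5 (the walk either steps
  # to 2 immediately or terminates; revisits cannot help once absorbed)
  cyc <- scale_to_transition(
    segment_table(c(1L, 2L), c(2L, 1L), c(100, 100)), safety = 0.5
  )
  expect_equal(analytic_visit_probability(cyc, 1L, 2L), 0.5)
  expect_error(analytic_visit_probability(chain, 2L, 2L), "i != j")
})

test_that("increasing travel on a segment weakly increases visit probability", {
  base <- random_segment_table(12, seed = 33, density = 0.3)
  tm <- scale_to_transition(base)
  row_sum <- tapply(base$weight, base$cell_i, sum)
  busiest <- as.integer(names(row_sum)[which.max(row_sum)])
  # bump a segment in a non-maximal row so lambda_t stays fixed
  k <- which(base$cell_i != busiest)[1]
  bumped <- base
  bumped$weight[k] <- bumped$weight[k] + 0.5 * (max(row_sum) - row_sum[as.character(base$cell_i[k])])
  tm2 <- scale_to_transition(bumped)
  expect_equal(tm2$lambda, tm$lambda)
  i <- base$cell_i[k]; j <- base$cell_j[k]
  expect_gte(analytic_visit_probability(tm2, i, j) + 1e-12,
             analytic_visit_probability(tm, i, j))
})

test_that("walk lengths follow the geometric termination bound", {
  # symmetric two-node cycle with p = 0.9: steps ~ geometric, mean 9
  cyc <- scale_to_transition(
    segment_table(c(1L, 2L), c(2L, 1L), c(100, 100)), safety = 0.9
  )
  n <- 20000
  lens <- vapply(seq_len(n), function(s) {
    length(simulate_path(cyc, 1L, seed = s)$visited)
  }, numeric(1))
  mean_len <- mean(lens)
  se <- sqrt(0.9 / 0.1^2) / sqrt(n)
  expect_lt(abs(mean_len - 9), 3 * se)
  # hard bound from the row-sum constraint
  expect_lte(mean_len, 1 / (1 - 0.9) + 3 * se)
})

test_that("risk matrices round-trip through sparse CSV with metadata", {
  tm <- scale_to_transition(random_segment_table(10, seed = 2))
  phi <- estimate_phi(tm, sims_per_origin = 500, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_risk_matrix(phi, path)
  back <- read_risk_matrix(path)
  expect_equal(df_plain(back), df_plain(phi))
  expect_equal(attr(back, "sims_per_origin"), attr(phi, "sims_per_origin"))
  expect_equal(attr(back, "origins"), attr(phi, "origins"))
})
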