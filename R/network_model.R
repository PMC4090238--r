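# Travel matrix M, scaled transition model P_t, stochastic pathway
# simulation of phi_ij, and the exact hitting-probability cross-check.

#' Validate a segment table as the travel matrix
#'
#' Fixes the node set of the sparse travel-frequency matrix and checks the
#' structural invariants: no diagonal entries (diagonal elements are defined
#' as zero) and strictly positive weights. Nodes that only ever appear as
#' destinations are legitimate: they simply have no outgoing row.
#'
#' @param segments A `segment_table` (or plain tibble with `cell_i`,
#'   `cell_j`, `weight`).
#' @return The validated `segment_table` with a `nodes` attribute holding
#'   the sorted node set.
#' @export
build_travel_matrix <- function(segments) {
  df <- tibble::as_tibble(segments)
  if (!all(c("cell_i", "cell_j", "weight") %in% names(df))) {
    stop("segments must have columns cell_i, cell_j, weight", call. = FALSE)
  }
  if (any(df$cell_i == df$cell_j)) {
    bad <- df$cell_i[df$cell_i == df$cell_j][1]
    stop("diagonal entry (", bad, ", ", bad,
         ") not allowed: diagonal elements of the travel matrix are zero",
         call. = FALSE)
  }
  if (any(!is.finite(df$weight) | df$weight <= 0)) {
    stop("travel matrix weights must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(paste(df$cell_i, df$cell_j))) {
    stop("duplicate (i, j) pairs in travel matrix", call. = FALSE)
  }
  out <- new_segment_table(df, period = attr(segments, "period"))
  attr(out, "nodes") <- sort(unique(c(out$cell_i, out$cell_j)))
  out
}

#' Scale the travel matrix into a transition model
#'
#' Converts trip frequencies into per-segment transition values
#' `p_ij = lambda_t * m_ij`, with the scaling parameter chosen as
#' `lambda_t = safety / max(row sums of M)` so that every row of the
#' transition matrix sums below 1 (the sole structural requirement on
#' `lambda_t`). Each node's remaining mass is its termination probability
#' `p_i_term = 1 - sum_j p_ij`; destination-only nodes get `p_i_term = 1`
#' and never act as origins.
#'
#' @param M A validated travel matrix from [build_travel_matrix()] (a plain
#'   `segment_table` is validated on the fly).
#' @param safety Fraction of the unit row-sum budget given to the busiest
#'   row, in (0, 1). Default 0.9. Larger values sharpen relative contrasts
#'   in simulated risk; the requirement is only that row sums stay below 1.
#' @return An object of class `transition_model` with elements `p` (tibble
#'   `cell_i`, `cell_j`, `p_ij`), `lambda`, `safety`, `p_term` (tibble
#'   `cell`, `p_term`), and `nodes`.
#' @export
scale_to_transition <- function(M, safety = 0.9) {
  if (!is.numeric(safety) || length(safety) != 1L || safety <= 0 || safety >= 1) {
    stop("`safety` must be a single number in (0, 1)", call. = FALSE)
  }
  M <- build_travel_matrix(M)
  if (nrow(M) == 0L) {
    stop("cannot scale an all-zero travel matrix: lambda_t is undefined",
         call. = FALSE)
  }
  nodes <- attr(M, "nodes")
  row_sum <- tapply(M$weight, factor(M$cell_i, levels = nodes), sum,
                    default = 0)
  lambda <- safety / max(row_sum)
  p <- tibble::tibble(
    cell_i = M$cell_i, cell_j = M$cell_j,
    p_ij = lambda * M$weight
  )
  p_sum <- tapply(p$p_ij, factor(p$cell_i, levels = nodes), sum, default = 0)
  model <- structure(
    list(
      p = dplyr::arrange(p, .data$cell_i, .data$cell_j),
      lambda = lambda,
      safety = safety,
      p_term = tibble::tibble(cell = nodes, p_term = as.numeric(1 - p_sum)),
      nodes = nodes
    ),
    class = "transition_model"
  )
  model$csr <- transition_csr(model)
  model
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "<transition_model> %d nodes, %d segments, lambda_t = %.6g (safety %.2f)\n",
    length(x$nodes), nrow(x$p), x$lambda, x$safety
  ))
  cat(sprintf("  origin nodes (p_term < 1): %d\n", sum(x$p_term$p_term < 1)))
  invisible(x)
}

# Compressed sparse-row view used by the compiled walker: nodes mapped to
# 0-based indices, per-row cumulative transition probabilities.
transition_csr <- function(model) {
  nodes <- model$nodes
  n <- length(nodes)
  i <- match(model$p$cell_i, nodes) - 1L
  j <- match(model$p$cell_j, nodes) - 1L
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]
  p <- model$p$p_ij[ord]
  row_ptr <- c(0L, cumsum(tabulate(i + 1L, nbins = n)))
  cum <- p
  for (k in seq_len(n)) {
    lo <- row_ptr[k] + 1L; hi <- row_ptr[k + 1L]
    if (hi >= lo) cum[lo:hi] <- cumsum(p[lo:hi])
  }
  list(row_ptr = as.integer(row_ptr), col_idx = as.integer(j), cum = cum, n = n)
}

#' Simulate a single camper itinerary
#'
#' Runs one absorbing random walk from an origin cell: at each node the next
#' cell is drawn with its transition probability, and the walk ends either
#' on a terminal (no-travel) draw or upon reaching a cell with no outgoing
#' travel. A hard step cap guards against pathological configurations.
#'
#' @param model A [scale_to_transition()] model.
#' @param origin Origin cell id (must be a model node).
#' @param seed Integer seed; the walk uses a substream derived from
#'   `(seed, origin)`, so replaying the same pair reproduces the path.
#' @param max_steps Step cap, default 10000 (unreachable in practice since
#'   row sums are below 1).
#' @return An object of class `path_sample`: list with `origin`, `visited`
#'   (cell ids in order, after the origin) and `termination` (one of
#'   `"terminal_draw"`, `"no_outgoing"`, `"capped"`).
#' @export
simulate_path <- function(model, origin, seed, max_steps = 10000L) {
  stopifnot(inherits(model, "transition_model"))
  idx <- match(origin, model$nodes)
  if (length(origin) != 1L || is.na(idx)) {
    stop("origin ", origin[1], " is not a node of the model", call. = FALSE)
  }
  csr <- model$csr
  res <- cpp_walk_path(csr$row_ptr, csr$col_idx, csr$cum, idx - 1L,
                       as.double(seed), as.integer(max_steps))
  structure(
    list(
      origin = origin,
      visited = model$nodes[res$path + 1L],
      termination = c("terminal_draw", "no_outgoing", "capped")[res$termination + 1L]
    ),
    class = "path_sample"
  )
}

#' @export
print.path_sample <- function(x, ...) {
  cat(sprintf("<path_sample> origin %d -> %s (%s)\n", x$origin,
              if (length(x$visited)) paste(x$visited, collapse = " -> ") else "(stayed)",
              x$termination))
  invisible(x)
}

#' Estimate pairwise dispersal risk by stochastic pathway simulation
#'
#' For each origin cell, simulates `sims_per_origin` independent itineraries
#' and tallies, for every other cell, the number of walks that visit it at
#' least once (`M_ij`). Intermediate and final destinations both count, so
#' multi-destination itineraries contribute to every cell they touch. The
#' relative dispersal risk is `phi_ij = M_ij / M` with `M = sims_per_origin`,
#' an indicator-based proportion bounded in \[0, 1\]. The origin itself is
#' never counted, so `phi_ii` is absent (conventionally 0).
#'
#' @param model A [scale_to_transition()] model.
#' @param origins Cell ids to simulate from; default all model nodes with
#'   `p_term < 1` (nodes with outgoing travel).
#' @param sims_per_origin Number of walks per origin (>= 1).
#' @param seed Integer seed; each origin uses an independent substream
#'   derived from `(seed, origin)`, so results do not depend on origin
#'   processing order.
#' @param max_steps Per-walk step cap, default 10000; cap hits are counted
#'   in the result's `cap_hits` attribute.
#' @return A `risk_matrix`: a tibble with columns `cell_i`, `cell_j`,
#'   `hits` (`M_ij`) and `phi`, keeping only positive entries, with
#'   attributes `sims_per_origin`, `seed`, `origins` and `cap_hits`.
#' @export
estimate_phi <- function(model, origins = NULL, sims_per_origin = 10000L,
                         seed = 1L, max_steps = 10000L) {
  stopifnot(inherits(model, "transition_model"))
  if (!is.numeric(sims_per_origin) || sims_per_origin < 1) {
    stop("`sims_per_origin` must be >= 1", call. = FALSE)
  }
  if (is.null(origins)) {
    origins <- model$p_term$cell[model$p_term$p_term < 1]
  }
  unknown <- setdiff(origins, model$nodes)
  if (length(unknown) > 0) {
    stop("origin ", unknown[1], " is not a node of the model", call. = FALSE)
  }
  csr <- model$csr
  sims <- as.integer(sims_per_origin)
  cap_hits <- 0L
  rows <- purrr::map(origins, function(o) {
    idx <- match(o, model$nodes) - 1L
    res <- cpp_walk_counts(csr$row_ptr, csr$col_idx, csr$cum, csr$n,
                           idx, sims, as.double(seed), as.integer(max_steps))
    cap_hits <<- cap_hits + res$cap_hits
    hit <- which(res$counts > 0L)
    tibble::tibble(
      cell_i = rep(o, length(hit)),
      cell_j = model$nodes[hit],
      hits = res$counts[hit]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(cell_i = integer(), cell_j = integer(), hits = integer())
  }
  out$phi <- out$hits / sims
  structure(
    dplyr::arrange(out, .data$cell_i, .data$cell_j),
    sims_per_origin = sims, seed = as.integer(seed),
    origins = as.integer(origins), cap_hits = cap_hits,
    class = c("risk_matrix", class(tibble::tibble()))
  )
}

#' @export
print.risk_matrix <- function(x, ...) {
  cat(sprintf(
    "<risk_matrix> %d positive pairs from %d origins, %d walks per origin\n",
    nrow(x), length(attr(x, "origins")), attr(x, "sims_per_origin")
  ))
  NextMethod()
}

#' Exact visit probability by linear solve
#'
#' Computes analytically the probability that an itinerary starting at
#' `origin` ever visits `target`: the hitting probability
#' `h(k) = p_k,target + sum_{l != target} p_kl h(l)`, solved as a sparse
#' linear system. Because every row of the transition matrix sums below 1,
#' the system is strictly diagonally dominant and never singular. This is
#' the exact counterpart of the simulated `phi_ij` and serves as its
#' cross-check.
#'
#' @param model A [scale_to_transition()] model.
#' @param origin One or more origin cell ids (none equal to `target`).
#' @param target Target cell id.
#' @return Numeric vector of visit probabilities, one per origin.
#' @export
analytic_visit_probability <- function(model, origin, target) {
  stopifnot(inherits(model, "transition_model"))
  if (length(target) != 1L || !target %in% model$nodes) {
    stop("target ", target[1], " is not a node of the model", call. = FALSE)
  }
  if (any(origin == target)) {
    stop("origin equal to target: visit probability is defined for i != j",
         call. = FALSE)
  }
  unknown <- setdiff(origin, model$nodes)
  if (length(unknown) > 0) {
    stop("origin ", unknown[1], " is not a node of the model", call. = FALSE)
  }
  h <- hitting_probabilities(model, target)
  unname(h[as.character(origin)])
}

# Hitting probabilities of `target` from every other node, as a named
# vector. One sparse solve per target.
hitting_probabilities <- function(model, target) {
  nodes <- model$nodes
  n <- length(nodes)
  t_idx <- match(target, nodes)
  i <- match(model$p$cell_i, nodes)
  j <- match(model$p$cell_j, nodes)
  P <- Matrix::sparseMatrix(i = i, j = j, x = model$p$p_ij, dims = c(n, n))
  keep <- setdiff(seq_len(n), t_idx)
  if (length(keep) == 0L) return(stats::setNames(numeric(0), character(0)))
  Q <- P[keep, keep, drop = FALSE]
  b <- P[keep, t_idx, drop = FALSE]
  A <- Matrix::Diagonal(length(keep)) - Q
  h <- as.numeric(Matrix::solve(A, b))
  stats::setNames(pmin(1, pmax(0, h)), nodes[keep])
}

#' Read and write risk matrices as sparse CSV
#'
#' Serialises `phi` estimates as CSV columns `cell_i`, `cell_j`, `hits`,
#' `phi` plus a JSON sidecar (same path with extension `.json`) holding the
#' simulation metadata; values round-trip exactly.
#'
#' @param phi A `risk_matrix`.
#' @param path CSV file path.
#' @return `write_risk_matrix()` returns `path` invisibly;
#'   `read_risk_matrix()` returns a `risk_matrix`.
#' @export
write_risk_matrix <- function(phi, path) {
  stopifnot(inherits(phi, "risk_matrix"))
  readr::write_csv(tibble::as_tibble(phi)[c("cell_i", "cell_j", "hits", "phi")], path)
  meta <- list(
    sims_per_origin = attr(phi, "sims_per_origin"),
    seed = attr(phi, "seed"),
    origins = attr(phi, "origins"),
    cap_hits = attr(phi, "cap_hits")
  )
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_matrix
#' @export
read_risk_matrix <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      cell_i = readr::col_integer(), cell_j = readr::col_integer(),
      hits = readr::col_integer(), phi = readr::col_double()
    ),
    progress = FALSE
  )
  df <- tibble::tibble(cell_i = df$cell_i, cell_j = df$cell_j,
                       hits = df$hits, phi = df$phi)
  meta_path <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(sims_per_origin = NA_integer_, seed = NA_integer_,
         origins = unique(df$cell_i), cap_hits = NA_integer_)
  }
  structure(
    df,
    sims_per_origin = meta$sims_per_origin, seed = meta$seed,
    origins = as.integer(meta$origins), cap_hits = meta$cap_hits,
    class = c("risk_matrix", class(tibble::tibble()))
  )
}
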