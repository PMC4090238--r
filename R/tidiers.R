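# broom-style tidiers for fitted model objects.

#' Tidy a transition model
#'
#' One row per network segment with its transition probability.
#'
#' @param x A [scale_to_transition()] model.
#' @param ... Unused.
#' @return A tibble with columns `cell_i`, `cell_j`, `p_ij`.
#' @export
tidy.transition_model <- function(x, ...) {
  tibble::as_tibble(x$p)
}

#' @rdname tidy.transition_model
#' @return For `glance()`: a one-row tibble with `n_nodes`, `n_segments`,
#'   `lambda`, `safety`, `max_row_sum`, `n_origin_nodes`.
#' @export
glance.transition_model <- function(x, ...) {
  row_sum <- tapply(x$p$p_ij, factor(x$p$cell_i, levels = x$nodes), sum,
                    default = 0)
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_segments = nrow(x$p),
    lambda = x$lambda,
    safety = x$safety,
    max_row_sum = max(row_sum),
    n_origin_nodes = sum(x$p_term$p_term < 1)
  )
}

#' Tidy a risk matrix
#'
#' One row per positive origin-destination risk estimate.
#'
#' @param x A `risk_matrix` from [estimate_phi()].
#' @param ... Unused.
#' @return A tibble with columns `cell_i`, `cell_j`, `hits`, `phi`.
#' @export
tidy.risk_matrix <- function(x, ...) {
  tibble::as_tibble(x)[c("cell_i", "cell_j", "hits", "phi")]
}

#' @rdname tidy.risk_matrix
#' @return For `glance()`: a one-row tibble with `n_origins`,
#'   `sims_per_origin`, `n_positive_pairs`, `max_phi`, `cap_hits`, `seed`.
#' @export
glance.risk_matrix <- function(x, ...) {
  tibble::tibble(
    n_origins = length(attr(x, "origins")),
    sims_per_origin = attr(x, "sims_per_origin"),
    n_positive_pairs = nrow(x),
    max_phi = if (nrow(x) > 0) max(x$phi) else 0,
    cap_hits = attr(x, "cap_hits"),
    seed = attr(x, "seed")
  )
}
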