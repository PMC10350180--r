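#' Margin-preserving swap randomization of a count matrix
#'
#' Generates the single-class "continuum" null by stochastic pairwise
#' swapping of axonal counts: each accepted move picks two distinct
#' neurons (rows) i, j and two distinct regions (columns) a, b uniformly
#' and transfers one unit of count, (i,a)-1, (i,b)+1, (j,a)+1, (j,b)-1.
#' Moves that would drive any cell negative are rejected and do not count
#' towards `n_swaps`. Row sums (axonal size per neuron) and column sums
#' (regional targeting) are preserved exactly.
#'
#' The chain uses R's random number generator, so results are reproducible
#' under `set.seed()` or via the `seed` argument.
#'
#' @param matrix neuron-by-region matrix of non-negative integer counts
#'   with at least 2 rows and 2 columns.
#' @param n_swaps number of accepted unit moves; defaults to 10 times the
#'   total count in the matrix (generous mixing at typical sizes).
#' @param seed optional integer seed applied locally.
#' @param max_proposals safety cap on proposals (default `1e6 + 1000 *
#'   n_swaps`); matrices whose support admits no legal move would
#'   otherwise loop forever. Hitting the cap raises a warning.
#' @return randomized matrix with identical dimnames, row sums and column
#'   sums, and attributes `accepted`, `proposals`, `acceptance_rate`.
#' @export
swap_randomize <- function(matrix, n_swaps = NULL, seed = NULL,
                           max_proposals = NULL) {
  validate_projection_matrix(matrix)
  if (nrow(matrix) < 2L || ncol(matrix) < 2L) {
    stop("null model undefined: swap randomization needs at least two ",
         "neurons and two regions (got ", nrow(matrix), " x ",
         ncol(matrix), ")")
  }
  if (any(matrix != round(matrix))) {
    stop("swap randomization requires integer counts")
  }
  n_swaps <- n_swaps %||% (10 * sum(matrix))
  if (n_swaps < 1) stop("n_swaps must be at least 1")
  max_proposals <- max_proposals %||% (1e6 + 1000 * n_swaps)
  storage <- matrix(as.integer(round(matrix)), nrow = nrow(matrix),
                    dimnames = dimnames(matrix))
  out <- with_seed(seed,
                   swap_randomize_cpp(storage, n_swaps, max_proposals))
  accepted <- attr(out, "accepted")
  proposals <- attr(out, "proposals")
  if (accepted < n_swaps) {
    warning("swap chain reached the proposal cap after ", accepted,
            " accepted moves (requested ", n_swaps, ")")
  }
  res <- matrix(as.numeric(out), nrow = nrow(out),
                dimnames = dimnames(matrix))
  attr(res, "accepted") <- accepted
  attr(res, "proposals") <- proposals
  attr(res, "acceptance_rate") <- accepted / proposals
  res
}

#' Pooled null distribution of pairwise angles
#'
#' Pools the pairwise arccosine distances of `n_replicates` independent
#' swap-randomized copies of `matrix`. With one replicate (the default)
#' this is the angle distribution of a single randomized matrix.
#'
#' @inheritParams swap_randomize
#' @param n_replicates number of independent randomized matrices whose
#'   angle distributions are pooled.
#' @return an `angle_distribution` (see [pairwise_angles()]) whose
#'   `n_items` refers to one replicate.
#' @export
null_angle_distribution <- function(matrix, n_swaps = NULL,
                                    n_replicates = 1, seed = NULL) {
  with_seed(seed, {
    pooled <- unlist(lapply(seq_len(n_replicates), function(r) {
      rm <- swap_randomize(matrix, n_swaps = n_swaps)
      keep <- rowSums(rm) > 0  # a row can in principle be swapped empty only
      # if it started empty; positive rows stay positive (sums preserved)
      pairwise_angles(rm[keep, , drop = FALSE])$angles
    }))
    structure(list(angles = pooled, n_items = nrow(matrix),
                   n_replicates = n_replicates),
              class = "angle_distribution")
  })
}
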