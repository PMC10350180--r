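# Synthetic data with the statistical structure the classifier assumes:
# class-structured count matrices, toy morphologies with region-labelled
# axonal tips at controlled path distances, and class-specific soma
# clouds. Used by the test suite and the `simulate` CLI command.

#' Block-structured class projection profiles
#'
#' Each class receives a distinct block of regions; `within_mass` of its
#' probability mass is spread over its block and the remainder over a
#' shared background, both with a 1/rank decay so that a few regions
#' dominate, as in real projectomes. With one class the profile is the
#' background alone.
#'
#' @param k_classes number of classes.
#' @param n_regions number of regions (at least `k_classes`).
#' @param within_mass probability mass on the class's own block; the
#'   effect size separating classes.
#' @return matrix (classes x regions) of probabilities, rows summing to 1.
#' @export
synthetic_profiles <- function(k_classes, n_regions,
                               within_mass = 0.8) {
  if (n_regions < k_classes) stop("need at least one region per class")
  shared <- (1 / seq_len(n_regions))
  shared <- shared / sum(shared)
  if (k_classes == 1L) {
    out <- matrix(shared, 1L, n_regions)
  } else {
    blocks <- split(seq_len(n_regions),
                    rep(seq_len(k_classes), length.out = n_regions))
    out <- t(vapply(seq_len(k_classes), function(cl) {
      block <- blocks[[cl]]
      p <- (1 - within_mass) * shared
      w <- 1 / seq_along(block)
      p[block] <- p[block] + within_mass * w / sum(w)
      p
    }, numeric(n_regions)))
  }
  dimnames(out) <- list(paste0("K", seq_len(k_classes)),
                        sprintf("R%02d", seq_len(n_regions)))
  out
}

#' Generate a class-structured synthetic count matrix
#'
#' Per neuron: a total axonal point count is drawn log-normally, region
#' proportions are the neuron's class profile (optionally jittered with a
#' Dirichlet draw to add over-dispersion), and counts are multinomial.
#' The default `concentration = Inf` uses the class profile directly
#' (pure multinomial sampling): under this framework's null, within-class
#' variation beyond counting noise is itself class structure, so the
#' single-class default carries none. Finite `concentration` (the
#' Dirichlet precision, larger = tighter) emulates biological
#' over-dispersion.
#'
#' @param k_classes number of planted classes.
#' @param n_per_class neurons per class (scalar or length-k vector).
#' @param n_regions number of regions.
#' @param profiles optional (classes x regions) probability matrix;
#'   defaults to [synthetic_profiles()] with `within_mass`.
#' @param within_mass effect size passed to [synthetic_profiles()].
#' @param concentration Dirichlet precision (`Inf` = multinomial).
#' @param size_meanlog,size_sdlog log-normal parameters of the per-neuron
#'   total axonal point count (defaults: median 1000 points, sdlog 0.5,
#'   the order of magnitude of whole-brain reconstruction node counts).
#' @param seed integer seed (applied locally).
#' @return list with `matrix` (counts, neurons x regions), `assignment`
#'   (true classes, data frame `neuron_id`, `class`) and `profiles`.
#' @export
generate_matrix <- function(k_classes = 2, n_per_class = 20,
                            n_regions = 12, profiles = NULL,
                            within_mass = 0.8, concentration = Inf,
                            size_meanlog = log(1000), size_sdlog = 0.5,
                            seed = NULL) {
  profiles <- profiles %||%
    synthetic_profiles(k_classes, n_regions, within_mass)
  if (nrow(profiles) != k_classes) {
    stop("profiles must have one row per class")
  }
  n_regions <- ncol(profiles)
  n_per_class <- rep(n_per_class, length.out = k_classes)
  with_seed(seed, {
    truth <- rep(seq_len(k_classes), times = n_per_class)
    n <- length(truth)
    totals <- pmax(1, round(stats::rlnorm(n, size_meanlog, size_sdlog)))
    counts <- t(vapply(seq_len(n), function(i) {
      p <- profiles[truth[i], ]
      if (is.finite(concentration)) {
        g <- stats::rgamma(n_regions, shape = p * concentration)
        if (sum(g) == 0) g[which.max(p)] <- 1
        p <- g / sum(g)
      }
      as.numeric(stats::rmultinom(1L, totals[i], p))
    }, numeric(n_regions)))
    dimnames(counts) <- list(sprintf("N%03d", seq_len(n)),
                             colnames(profiles))
    list(matrix = counts,
         assignment = data.frame(neuron_id = rownames(counts),
                                 class = rownames(profiles)[truth],
                                 stringsAsFactors = FALSE),
         profiles = profiles)
  })
}

#' Generate a matrix from the single-class continuum null
#'
#' Draws a matrix from the classifier's own null hypothesis: a
#' single-profile multinomial seed matrix mixed by a long burn-in of
#' margin-preserving swaps, i.e. (approximately) a uniform draw from the
#' set of count matrices with the seed's row and column sums. Useful for
#' studying the variance gate's behaviour under its exact null.
#'
#' @inheritParams generate_matrix
#' @param burnin_factor accepted burn-in swaps as a multiple of the total
#'   count.
#' @return list with `matrix` and `assignment` (all neurons in one class).
#' @export
generate_null_matrix <- function(n_neurons = 50, n_regions = 12,
                                 size_meanlog = log(1000),
                                 size_sdlog = 0.5, burnin_factor = 20,
                                 seed = NULL) {
  with_seed(seed, {
    seed_mat <- generate_matrix(k_classes = 1, n_per_class = n_neurons,
                                n_regions = n_regions,
                                size_meanlog = size_meanlog,
                                size_sdlog = size_sdlog)$matrix
    m <- swap_randomize(seed_mat, n_swaps = burnin_factor * sum(seed_mat))
    list(matrix = m,
         assignment = data.frame(neuron_id = rownames(m), class = "K1",
                                 stringsAsFactors = FALSE))
  })
}

# Deterministic, well-spread unit direction for region index i (spherical
# Fibonacci lattice); synthetic axonal branches extend along these rays.
region_direction <- function(i, n) {
  golden <- (1 + sqrt(5)) / 2
  zc <- 1 - 2 * (i - 0.5) / max(n, 1)
  theta <- 2 * pi * i / golden
  r <- sqrt(max(0, 1 - zc^2))
  c(r * cos(theta), r * sin(theta), zc)
}

#' Generate toy morphologies with controlled path distances
#'
#' Builds one rooted tree per neuron: the soma is drawn from its class's
#' Gaussian cloud, and for each region with a positive planted count the
#' neuron grows a straight branch along a fixed region-specific direction
#' carrying that many axonal points. The points are placed so that, with
#' zero noise, the per-neuron *median* path distance to the region equals
#' the configured class/region offset exactly (points sit at the offset
#' plus/minus multiples of `spacing`). Because branches are straight rays
#' from the soma, path distance equals Euclidean distance here; real
#' axons are tortuous, which only increases path distances.
#'
#' Layer labels are assigned by thresholding the soma coordinate along
#' `layer_axis` at `layer_breaks` (labels `"L1"`, `"L2"`, ... from low to
#' high coordinate); without breaks every soma is labelled `"L1"`.
#'
#' @param counts neuron-by-region matrix of planted axonal point counts
#'   (small integers; e.g. a down-scaled [generate_matrix()] output).
#' @param assignment data frame `neuron_id`, `class` covering the rows.
#' @param soma_centers (classes x 3) matrix of class soma cloud centres
#'   (um), rownames = class labels; default spaces classes 500 um apart
#'   along x.
#' @param soma_sd isotropic soma cloud standard deviation (um).
#' @param offsets (classes x regions) matrix of target path-length
#'   offsets (um); default `3000 + 400 * (region index - 1)` for every
#'   class.
#' @param offset_noise_sd per-point Gaussian jitter on path lengths (um).
#' @param spacing spacing of consecutive points on a branch (um).
#' @param source_parcel parcel id given to the soma.
#' @param layer_axis,layer_breaks layer assignment (see above).
#' @param seed integer seed (applied locally).
#' @return list with `neurons` (list of [neuron_reconstruction()]) and
#'   `somata` (data frame `neuron_id`, `class`, `x`, `y`, `z`, `layer`).
#' @export
generate_morphologies <- function(counts, assignment,
                                  soma_centers = NULL, soma_sd = 100,
                                  offsets = NULL, offset_noise_sd = 0,
                                  spacing = 10, source_parcel = "SRC",
                                  layer_axis = "y", layer_breaks = NULL,
                                  seed = NULL) {
  validate_projection_matrix(counts)
  assignment <- validate_assignment(assignment, rownames(counts))
  classes <- sort(unique(assignment$class))
  regions <- colnames(counts)
  if (is.null(soma_centers)) {
    soma_centers <- cbind(500 * (seq_along(classes) - 1), 0, 0)
    rownames(soma_centers) <- classes
  }
  if (is.null(offsets)) {
    offsets <- matrix(rep(3000 + 400 * (seq_along(regions) - 1),
                          each = length(classes)),
                      nrow = length(classes),
                      dimnames = list(classes, regions))
  }
  if (!all(classes %in% rownames(soma_centers)) ||
      !all(classes %in% rownames(offsets))) {
    stop("soma_centers and offsets must have one row per class")
  }
  max_counts <- apply(counts, 2L, max)
  min_off <- apply(offsets[classes, , drop = FALSE], 2L, min)
  too_close <- min_off <= spacing * (max_counts + 1) / 2
  if (any(too_close)) {
    stop("offset too small for spacing and counts in region(s): ",
         paste(regions[too_close], collapse = ", "))
  }

  dirs <- t(vapply(seq_along(regions), region_direction,
                   numeric(3), n = length(regions)))
  with_seed(seed, {
    neurons <- vector("list", nrow(counts))
    somata <- vector("list", nrow(counts))
    for (i in seq_len(nrow(counts))) {
      id <- rownames(counts)[i]
      cls <- assignment$class[assignment$neuron_id == id]
      soma_xyz <- soma_centers[cls, ] + stats::rnorm(3, 0, soma_sd)
      nodes <- data.frame(node_id = 1L, x = soma_xyz[1L],
                          y = soma_xyz[2L], z = soma_xyz[3L],
                          parent_id = NA_integer_, structure = "soma",
                          parcel_id = source_parcel,
                          stringsAsFactors = FALSE)
      next_id <- 2L
      for (r in seq_along(regions)) {
        cnt <- counts[i, r]
        if (cnt < 1) next
        d <- offsets[cls, r] +
          spacing * (seq_len(cnt) - (cnt + 1) / 2)
        if (offset_noise_sd > 0) {
          d <- d + stats::rnorm(cnt, 0, offset_noise_sd)
        }
        d <- sort(pmax(d, spacing / 2))
        ids <- next_id:(next_id + cnt - 1L)
        nodes <- rbind(nodes, data.frame(
          node_id = ids,
          x = soma_xyz[1L] + d * dirs[r, 1L],
          y = soma_xyz[2L] + d * dirs[r, 2L],
          z = soma_xyz[3L] + d * dirs[r, 3L],
          parent_id = c(1L, ids[-length(ids)]),
          structure = "axon", parcel_id = regions[r],
          stringsAsFactors = FALSE))
        next_id <- next_id + cnt
      }
      layer <- if (is.null(layer_breaks)) "L1" else {
        paste0("L", findInterval(soma_xyz[match(layer_axis,
                                                c("x", "y", "z"))],
                                 sort(layer_breaks)) + 1L)
      }
      neurons[[i]] <- neuron_reconstruction(id, nodes,
                                            soma_layer = layer)
      somata[[i]] <- data.frame(neuron_id = id, class = cls,
                                x = soma_xyz[1L], y = soma_xyz[2L],
                                z = soma_xyz[3L], layer = layer,
                                stringsAsFactors = FALSE)
    }
    list(neurons = neurons, somata = do.call(rbind, somata))
  })
}
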