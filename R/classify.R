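#' Pairwise arccosine distances between neuron projection vectors
#'
#' The distance between two neurons is the angle (in degrees) between
#' their count vectors: the arccosine of the cosine similarity, clamped to
#' \[0, 180\] against floating-point overshoot. The angle is
#' scale-invariant, so it measures the difference in projection *pattern*
#' regardless of total axonal extent; proportional rows are at 0 degrees,
#' rows with disjoint region support at 90 degrees.
#'
#' @param matrix neuron-by-region count matrix; every row must have a
#'   positive norm.
#' @return object of class `angle_distribution`: a list with `angles`
#'   (numeric vector, one per unordered neuron pair, in the column order
#'   of `utils::combn`), `n_items` (number of neurons) and `labels`.
#' @export
pairwise_angles <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("pairwise_angles expects a numeric matrix")
  }
  if (nrow(matrix) < 2L) stop("need at least two neurons")
  norms <- sqrt(rowSums(matrix^2))
  if (any(norms == 0)) {
    bad <- rownames(matrix)[which(norms == 0)[1L]] %||%
      which(norms == 0)[1L]
    stop("zero-norm projection vector for neuron '", bad, "'")
  }
  unit <- matrix / norms
  cosine <- tcrossprod(unit)
  cosine <- pmin(pmax(cosine, -1), 1)
  ang <- acos(cosine) * 180 / pi
  structure(
    list(angles = ang[lower.tri(ang)], n_items = nrow(matrix),
         labels = rownames(matrix)),
    class = "angle_distribution"
  )
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat("<angle_distribution> ", length(x$angles), " pairwise angles over ",
      x$n_items, " items; mean ", round(mean(x$angles), 2), " deg, sd ",
      round(stats::sd(x$angles), 2), " deg\n", sep = "")
  invisible(x)
}

# Square symmetric angle matrix from a condensed angle_distribution.
angle_matrix <- function(distribution) {
  n <- distribution$n_items
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- distribution$angles
  m <- m + t(m)
  dimnames(m) <- list(distribution$labels, distribution$labels)
  m
}

#' One-tailed Levene variance test of real against null distances
#'
#' Tests whether the observed pairwise distance distribution has
#' significantly *larger* variance than the null distribution obtained by
#' swap randomization. The statistic is the classical Levene test on
#' absolute deviations from each group's mean (the "absolute" variant): a
#' one-way F statistic with (1, n_real + n_null - 2) degrees of freedom.
#' The one-tailed p-value is half the two-tailed p-value when the real
#' variance exceeds the null variance; when it does not, the p-value is
#' marked not applicable (`NA`) and the decision is `"stop"`, because the
#' alternative hypothesis is one-sided by design.
#'
#' @param real `angle_distribution` (or numeric vector) of observed
#'   pairwise distances.
#' @param null `angle_distribution` (or numeric vector) of null pairwise
#'   distances.
#' @param alpha significance level (default 0.05).
#' @return object of class `levene_result`: list with `var_real`,
#'   `var_null`, `statistic`, `df`, `p_one_tailed` (`NA` when not
#'   applicable), `alpha`, `decision` (`"split"`, `"stop"` or
#'   `"not_applicable"`) and `note`.
#' @export
levene_one_tailed <- function(real, null, alpha = 0.05) {
  x <- if (inherits(real, "angle_distribution")) real$angles else
    as.numeric(real)
  y <- if (inherits(null, "angle_distribution")) null$angles else
    as.numeric(null)
  if (length(x) < 2L || length(y) < 2L) {
    stop("both distributions need at least 2 values")
  }
  var_real <- stats::var(x)
  var_null <- stats::var(y)
  zx <- abs(x - mean(x))
  zy <- abs(y - mean(y))
  n1 <- length(zx)
  n2 <- length(zy)
  zbar <- mean(c(zx, zy))
  ssb <- n1 * (mean(zx) - zbar)^2 + n2 * (mean(zy) - zbar)^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  df2 <- n1 + n2 - 2L

  note <- NULL
  if (ssw == 0 && ssb == 0) {
    out <- list(var_real = var_real, var_null = var_null,
                statistic = NA_real_, df = c(1L, df2),
                p_one_tailed = NA_real_, alpha = alpha,
                decision = "stop",
                note = "degenerate: all absolute deviations identical")
    return(structure(out, class = "levene_result"))
  }
  f_stat <- if (ssw == 0) Inf else (ssb / 1) / (ssw / df2)
  p_two <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)
  if (var_real > var_null) {
    p_one <- p_two / 2
    decision <- if (p_one < alpha) "split" else "stop"
  } else {
    p_one <- NA_real_
    decision <- "stop"
    note <- "not applicable: real variance does not exceed null variance"
  }
  structure(
    list(var_real = var_real, var_null = var_null, statistic = f_stat,
         df = c(1L, df2), p_one_tailed = p_one, alpha = alpha,
         decision = decision, note = note),
    class = "levene_result"
  )
}

#' @export
print.levene_result <- function(x, ...) {
  p <- if (is.na(x$p_one_tailed)) "N/A" else format.pval(x$p_one_tailed)
  cat("<levene_result> var(real) = ", round(x$var_real, 2),
      ", var(null) = ", round(x$var_null, 2), ", one-tailed p = ", p,
      " -> ", x$decision, "\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Average-linkage (UPGMA) dendrogram over neurons
#'
#' Builds the hierarchical clustering tree of the neurons from their
#' pairwise angle distances with average linkage, the distance between
#' two clusters being the mean of all cross-pair distances.
#'
#' @param distribution `angle_distribution` from [pairwise_angles()] (or
#'   a `dist` object).
#' @return an object of class `hclust`.
#' @export
average_linkage <- function(distribution) {
  d <- if (inherits(distribution, "dist")) {
    distribution
  } else {
    if (distribution$n_items < 2L) stop("need at least two neurons")
    stats::as.dist(angle_matrix(distribution))
  }
  stats::hclust(d, method = "average")
}

#' Recursive variance-gated classification of projection neurons
#'
#' The core procedure: starting with all neurons in one class, each
#' candidate class is tested against the single-class null hypothesis. The
#' null is built from the candidate's *own* submatrix (columns restricted
#' to regions it actually targets) by margin-preserving swap
#' randomization; the observed and null pairwise arccosine distance
#' distributions are compared with the one-tailed Levene variance test.
#' If the observed variance is significantly larger, the candidate's
#' average-linkage dendrogram is cut at its root into two subtrees and the
#' procedure recurses on each; otherwise the candidate is accepted as a
#' class. Groups smaller than `min_testable` are terminal without testing
#' (too few pairwise distances to test a variance).
#'
#' Classes are labelled by a letter in decreasing order of class size
#' followed by the class size (e.g. `"A38"` for the largest class with 38
#' members).
#'
#' @param matrix neuron-by-region count matrix (integer counts, positive
#'   row sums).
#' @param alpha significance level of the Levene gate.
#' @param n_swaps accepted swap moves per null matrix; default 10 times
#'   the submatrix total.
#' @param n_replicates randomized matrices pooled per null distribution.
#' @param min_testable smallest group size that is still tested (>= 4).
#' @param seed optional integer seed; given the same matrix, parameters
#'   and seed the result is fully reproducible.
#' @return object of class `classification`: list with `tree` (nested
#'   nodes: `members`, `n`, `levene`, `note`, `children`), `assignment`
#'   (data frame `neuron_id`, `class` in matrix row order), `n_classes`,
#'   and `parameters`.
#' @export
classify_recursive <- function(matrix, alpha = 0.05, n_swaps = NULL,
                               n_replicates = 1, min_testable = 4,
                               seed = NULL) {
  validate_projection_matrix(matrix)
  if (min_testable < 4) stop("min_testable must be at least 4")
  if (any(rowSums(matrix) <= 0)) {
    stop("every neuron must have a positive total count; drop empty rows ",
         "during tabulation")
  }

  classify_node <- function(members) {
    node <- list(members = members, n = length(members), levene = NULL,
                 note = NULL, children = NULL)
    if (length(members) < min_testable) {
      node$note <- "terminal: below minimum testable size"
      return(node)
    }
    sub <- matrix[members, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    if (ncol(sub) < 2L) {
      node$note <- "terminal: fewer than two targeted regions"
      return(node)
    }
    real <- pairwise_angles(sub)
    if (all(real$angles == 0)) {
      node$note <- "terminal: all projection vectors proportional"
      return(node)
    }
    null <- null_angle_distribution(sub, n_swaps = n_swaps,
                                    n_replicates = n_replicates)
    gate <- levene_one_tailed(real, null, alpha = alpha)
    node$levene <- gate
    if (gate$decision != "split") {
      return(node)
    }
    hc <- average_linkage(real)
    halves <- stats::cutree(hc, k = 2)
    left <- members[halves == 1]
    right <- members[halves == 2]
    node$children <- list(classify_node(left), classify_node(right))
    node
  }

  tree <- with_seed(seed, classify_node(rownames(matrix)))

  leaves <- collect_leaves(tree)
  sizes <- vapply(leaves, length, integer(1))
  first_idx <- vapply(leaves, function(l) min(match(l, rownames(matrix))),
                      integer(1))
  ord <- order(-sizes, first_idx)
  labels <- paste0(class_letters(length(leaves)), sizes[ord])
  assignment <- data.frame(
    neuron_id = rownames(matrix),
    class = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(ord)) {
    assignment$class[assignment$neuron_id %in% leaves[[ord[i]]]] <-
      labels[i]
  }
  tree <- label_leaves(tree, leaves[ord], labels)

  structure(
    list(tree = tree, assignment = assignment,
         n_classes = length(leaves),
         parameters = list(alpha = alpha, n_swaps = n_swaps,
                           n_replicates = n_replicates,
                           min_testable = min_testable, seed = seed)),
    class = "classification"
  )
}

collect_leaves <- function(node) {
  if (is.null(node$children)) return(list(node$members))
  c(collect_leaves(node$children[[1L]]), collect_leaves(node$children[[2L]]))
}

label_leaves <- function(node, leaf_members, labels) {
  if (is.null(node$children)) {
    hit <- which(vapply(leaf_members, identical, logical(1), node$members))
    node$class <- labels[hit[1L]]
    return(node)
  }
  node$children <- lapply(node$children, label_leaves, leaf_members, labels)
  node
}

class_letters <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  reps <- ceiling(n / 26L)
  out <- unlist(lapply(seq_len(reps), function(r) {
    strrep(LETTERS, r)
  }))[seq_len(n)]
  out
}

#' @export
print.classification <- function(x, ...) {
  sizes <- table(x$assignment$class)
  cat("<classification> ", nrow(x$assignment), " neurons -> ",
      x$n_classes, " class(es): ",
      paste(names(sizes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a classification tree to JSON
#'
#' @param classification result of [classify_recursive()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(classification, path) {
  strip <- function(node) {
    out <- list(n = node$n, members = node$members)
    if (!is.null(node$class)) out$class <- node$class
    if (!is.null(node$note)) out$note <- node$note
    if (!is.null(node$levene)) {
      lv <- node$levene
      out$levene <- list(var_real = lv$var_real, var_null = lv$var_null,
                         statistic = lv$statistic,
                         p_one_tailed = lv$p_one_tailed,
                         decision = lv$decision)
    }
    if (!is.null(node$children)) {
      out$children <- lapply(node$children, strip)
    }
    out
  }
  jsonlite::write_json(
    list(n_classes = classification$n_classes,
         parameters = classification$parameters,
         tree = strip(classification$tree)),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Export a dendrogram in Newick format
#'
#' Writes the average-linkage dendrogram of a count matrix with merge
#' heights as branch lengths. Requires the `ape` package.
#'
#' @param matrix neuron-by-region count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dendrogram_newick <- function(matrix, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  hc <- average_linkage(pairwise_angles(matrix))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
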