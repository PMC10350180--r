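#' Validate a neuron-by-region count matrix
#'
#' Checks the invariants of a projection matrix: numeric, non-negative,
#' finite, unique neuron ids (row names) and unique region labels
#' (column names).
#'
#' @param m matrix to validate.
#' @return `m`, invisibly.
#' @export
validate_projection_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("projection matrix must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("projection matrix must carry neuron ids as row names and ",
         "region labels as column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate neuron ids")
  if (anyDuplicated(colnames(m))) stop("duplicate region labels")
  if (any(!is.finite(m))) stop("projection matrix has non-finite cells")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at neuron '", rownames(m)[bad[1L]],
         "', region '", colnames(m)[bad[2L]], "'")
  }
  invisible(m)
}

#' Tabulate axonal points per brain parcel
#'
#' Builds the neuron-by-region count matrix: cell (i, r) is the number of
#' axon-structure nodes of neuron i inside parcel r. All axonal nodes are
#' counted, not only branch or end points. Nodes with the sentinel parcel
#' `"unassigned"` are excluded from tabulation (but remain in the tree for
#' path-distance analyses).
#'
#' When `split_hemispheres` is set, each count is assigned an `ipsi` or
#' `contra` side by comparing the sign of (mediolateral coordinate -
#' `midline`) of the node with that of the neuron's soma; a node sitting
#' exactly on the midline counts as ipsilateral. Region labels then take
#' the form `"<parcel>|<side>"`.
#'
#' Parcels listed in `exclude_source` (typically the source region, whose
#' local collaterals would otherwise dominate every profile) are removed
#' from the matrix columns; their counts are returned separately in the
#' `"source_collaterals"` attribute.
#'
#' Neurons with no countable axonal node are reported and excluded
#' (attribute `"dropped"`).
#'
#' @param neurons list of [neuron_reconstruction()] objects sharing one
#'   atlas frame.
#' @param midline mediolateral coordinate of the midplane (micrometres);
#'   required when `split_hemispheres = TRUE`. Atlas-specific, never
#'   assumed.
#' @param split_hemispheres logical; split each parcel into ipsi/contra
#'   columns.
#' @param exclude_source character vector of parcel ids to exclude as
#'   source collaterals.
#' @param axis which coordinate is mediolateral: `"x"`, `"y"` or `"z"`.
#' @return count matrix (neurons x regions) with attributes
#'   `source_collaterals` (matrix or `NULL`), `dropped` (character),
#'   `split_hemispheres` (logical).
#' @export
tabulate_projections <- function(neurons, midline = NULL,
                                 split_hemispheres = FALSE,
                                 exclude_source = NULL, axis = "z") {
  if (!length(neurons)) stop("no neurons to tabulate")
  if (split_hemispheres) {
    stopifnot_scalar_number(midline, "midline")
    if (!axis %in% c("x", "y", "z")) stop("axis must be 'x', 'y' or 'z'")
  }
  rows <- lapply(neurons, function(nr) {
    nodes <- nr$nodes
    ax <- nodes[nodes$structure == "axon" &
                  nodes$parcel_id != "unassigned", , drop = FALSE]
    if (!nrow(ax)) {
      return(list(id = nr$neuron_id, counts = NULL))
    }
    if (split_hemispheres) {
      soma_side <- sign(soma_node(nr)[[axis]] - midline)
      if (soma_side == 0) soma_side <- 1
      node_side <- sign(ax[[axis]] - midline)
      node_side[node_side == 0] <- soma_side
      side <- ifelse(node_side == soma_side, "ipsi", "contra")
      lab <- make_region_label(ax$parcel_id, side)
    } else {
      lab <- ax$parcel_id
    }
    list(id = nr$neuron_id, counts = table(lab))
  })
  ids <- vapply(rows, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate neuron ids among reconstructions")
  empty <- vapply(rows, function(r) is.null(r$counts), logical(1))
  if (any(empty)) {
    warning("excluding neuron(s) with no countable axonal points: ",
            paste(ids[empty], collapse = ", "))
  }
  rows <- rows[!empty]
  if (!length(rows)) stop("no neuron has countable axonal points")
  labels <- sort(unique(unlist(lapply(rows, function(r) names(r$counts)))))
  m <- matrix(0, nrow = length(rows), ncol = length(labels),
              dimnames = list(ids[!empty], labels))
  for (r in rows) {
    m[r$id, names(r$counts)] <- as.numeric(r$counts)
  }

  collaterals <- NULL
  if (!is.null(exclude_source)) {
    parcels <- parse_region_labels(colnames(m))$parcel_id
    is_src <- parcels %in% exclude_source
    if (any(is_src)) {
      collaterals <- m[, is_src, drop = FALSE]
      m <- m[, !is_src, drop = FALSE]
    }
  }
  zero_rows <- rowSums(m) == 0
  dropped <- c(ids[empty], rownames(m)[zero_rows])
  if (any(zero_rows)) {
    warning("excluding neuron(s) with no extra-source axonal points: ",
            paste(rownames(m)[zero_rows], collapse = ", "))
    if (!is.null(collaterals)) {
      collaterals <- collaterals[!zero_rows, , drop = FALSE]
    }
    m <- m[!zero_rows, , drop = FALSE]
  }
  if (!nrow(m) || !ncol(m)) stop("tabulation produced an empty matrix")
  validate_projection_matrix(m)
  attr(m, "source_collaterals") <- collaterals
  attr(m, "dropped") <- dropped
  attr(m, "split_hemispheres") <- split_hemispheres
  m
}

#' Per-region projection profile of a class
#'
#' Sums the counts of the class's neurons in each region and divides by
#' the class total, yielding the fraction of the class's (extra-source)
#' axonal extent landing in each region. Fractions are non-negative and
#' sum to one.
#'
#' @param matrix neuron-by-region count matrix.
#' @param assignment data frame with columns `neuron_id`, `class`
#'   covering all matrix rows (as returned by [classify_recursive()]).
#' @param class_label the class to profile.
#' @return named numeric vector of per-region fractions.
#' @export
class_profile <- function(matrix, assignment, class_label) {
  validate_projection_matrix(matrix)
  assignment <- validate_assignment(assignment, rownames(matrix))
  members <- assignment$neuron_id[assignment$class == class_label]
  if (!length(members)) stop("class '", class_label, "' has no members")
  sub <- matrix[members, , drop = FALSE]
  total <- sum(sub)
  if (total <= 0) stop("class '", class_label, "' has zero total count")
  colSums(sub) / total
}

#' Projection profiles for every class
#'
#' @inheritParams class_profile
#' @return matrix (classes x regions) of per-region fractions; each row
#'   sums to one.
#' @export
class_profiles <- function(matrix, assignment) {
  assignment <- validate_assignment(assignment, rownames(matrix))
  classes <- sort(unique(assignment$class))
  out <- t(vapply(classes, function(cl) class_profile(matrix, assignment, cl),
                  numeric(ncol(matrix))))
  rownames(out) <- classes
  colnames(out) <- colnames(matrix)
  out
}

validate_assignment <- function(assignment, neuron_ids = NULL) {
  if (!is.data.frame(assignment) ||
      !all(c("neuron_id", "class") %in% names(assignment))) {
    stop("assignment must be a data frame with columns neuron_id, class")
  }
  assignment$neuron_id <- as.character(assignment$neuron_id)
  assignment$class <- as.character(assignment$class)
  if (anyDuplicated(assignment$neuron_id)) {
    stop("assignment has duplicate neuron ids")
  }
  if (!is.null(neuron_ids)) {
    missing_ids <- setdiff(neuron_ids, assignment$neuron_id)
    if (length(missing_ids)) {
      stop("assignment does not cover neuron(s): ",
           paste(utils::head(missing_ids, 5L), collapse = ", "))
    }
  }
  assignment
}
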