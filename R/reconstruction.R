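#' Construct a neuron reconstruction
#'
#' A reconstruction is a rooted tree of 3D points in a common atlas frame
#' (coordinates in micrometres). The root is the soma; every other node
#' carries a pointer to its parent. Each node is labelled with an atlas
#' parcel id (or the sentinel `"unassigned"`) and a structure class
#' (`soma`, `axon` or `dendrite`).
#'
#' Nodes are re-ordered topologically on construction so that every parent
#' precedes its children; an input containing a cycle, a dangling parent
#' reference or a disconnected node is rejected.
#'
#' @param neuron_id character scalar identifying the neuron.
#' @param nodes data frame with columns `node_id` (integer, unique),
#'   `x`, `y`, `z` (finite, micrometres), `parent_id` (integer, `NA` for
#'   the root), `structure` (one of `"soma"`, `"axon"`, `"dendrite"`) and
#'   `parcel_id` (character; `NA` is replaced by `"unassigned"`).
#' @param soma_layer optional layer label for the soma (e.g. `"L2"`).
#' @return an object of class `neuron_reconstruction`: a list with
#'   elements `neuron_id`, `nodes`, `soma_parcel_id`, `soma_layer`.
#' @export
neuron_reconstruction <- function(neuron_id, nodes, soma_layer = NULL) {
  required <- c("node_id", "x", "y", "z", "parent_id", "structure",
                "parcel_id")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols)) {
    stop("nodes is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  nodes <- nodes[, required]
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$parcel_id <- as.character(nodes$parcel_id)
  nodes$parcel_id[is.na(nodes$parcel_id) | nodes$parcel_id == ""] <-
    "unassigned"
  nodes$structure <- as.character(nodes$structure)

  coords <- as.matrix(nodes[, c("x", "y", "z")])
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    bad <- nodes$node_id[which(!apply(is.finite(coords), 1L, all))[1L]]
    stop("malformed reconstruction '", neuron_id,
         "': non-finite or missing coordinate at node ", bad)
  }
  if (anyDuplicated(nodes$node_id)) {
    stop("malformed reconstruction '", neuron_id, "': duplicate node ids")
  }
  bad_struct <- !nodes$structure %in% c("soma", "axon", "dendrite")
  if (any(bad_struct)) {
    stop("malformed reconstruction '", neuron_id,
         "': unknown structure at node ",
         nodes$node_id[which(bad_struct)[1L]])
  }
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1L) {
    stop("malformed reconstruction '", neuron_id, "': expected exactly one ",
         "root (parent_id = NA), found ", length(roots))
  }
  idx <- match(nodes$parent_id, nodes$node_id)
  dangling <- which(!is.na(nodes$parent_id) & is.na(idx))
  if (length(dangling)) {
    stop("malformed reconstruction '", neuron_id,
         "': dangling parent reference ", nodes$parent_id[dangling[1L]],
         " at node ", nodes$node_id[dangling[1L]])
  }

  # breadth-first ordering from the root; unreached nodes indicate a cycle
  n <- nrow(nodes)
  order_out <- integer(n)
  reached <- logical(n)
  order_out[1L] <- roots
  reached[roots] <- TRUE
  head <- 1L
  tail <- 1L
  children <- split(seq_len(n), factor(idx, levels = seq_len(n)))
  while (head <= tail) {
    kids <- children[[order_out[head]]]
    if (length(kids)) {
      order_out[(tail + 1L):(tail + length(kids))] <- kids
      reached[kids] <- TRUE
      tail <- tail + length(kids)
    }
    head <- head + 1L
  }
  if (tail != n) {
    stop("structural error in reconstruction '", neuron_id,
         "': cyclic parent chain involving node(s) ",
         paste(nodes$node_id[!reached][seq_len(min(3L, n - tail))],
               collapse = ", "))
  }
  nodes <- nodes[order_out, ]
  rownames(nodes) <- NULL

  structure(
    list(neuron_id = as.character(neuron_id),
         nodes = nodes,
         soma_parcel_id = nodes$parcel_id[1L],
         soma_layer = soma_layer),
    class = "neuron_reconstruction"
  )
}

#' @export
print.neuron_reconstruction <- function(x, ...) {
  tab <- table(x$nodes$structure)
  cat("<neuron_reconstruction> ", x$neuron_id, ": ", nrow(x$nodes),
      " nodes (", paste(names(tab), tab, sep = "=", collapse = ", "),
      "), soma parcel ", x$soma_parcel_id,
      if (!is.null(x$soma_layer)) paste0(", layer ", x$soma_layer), "\n",
      sep = "")
  invisible(x)
}

soma_node <- function(neuron) neuron$nodes[1L, ]

#' Path distances from the soma to every node
#'
#' Cable length along the reconstruction tree from the root (soma) to each
#' node, i.e. the sum of Euclidean segment lengths along the unique
#' root-to-node path. Always at least the straight-line distance.
#'
#' @param neuron a [neuron_reconstruction()].
#' @return numeric vector of distances in micrometres, named by node id,
#'   in the reconstruction's (topological) node order; the soma has
#'   distance 0.
#' @export
path_distances <- function(neuron) {
  nodes <- neuron$nodes
  idx <- match(nodes$parent_id, nodes$node_id)
  seg <- rep(0, nrow(nodes))
  has_parent <- !is.na(idx)
  dx <- nodes$x[has_parent] - nodes$x[idx[has_parent]]
  dy <- nodes$y[has_parent] - nodes$y[idx[has_parent]]
  dz <- nodes$z[has_parent] - nodes$z[idx[has_parent]]
  seg[has_parent] <- sqrt(dx^2 + dy^2 + dz^2)
  out <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))[-1L]) {
    out[i] <- out[idx[i]] + seg[i]
  }
  names(out) <- nodes$node_id
  out
}

#' Path distance from the soma to one node
#'
#' @param neuron a [neuron_reconstruction()].
#' @param node_id id of the target node.
#' @return distance in micrometres.
#' @export
path_distance <- function(neuron, node_id) {
  if (!node_id %in% neuron$nodes$node_id) {
    stop("node ", node_id, " does not exist in neuron ", neuron$neuron_id)
  }
  unname(path_distances(neuron)[as.character(node_id)])
}
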