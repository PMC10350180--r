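#' Leave-one-out convex hull outlier removal
#'
#' Flags soma positions whose removal changes the convex hull volume by
#' more than 1/n of the full-set hull volume: with full-set volume V over
#' n points, point p is an outlier iff |V - V(without p)| > V/n. By
#' default all points are screened in a single pass against the full-set
#' hull and flagged points are removed together; `sequential = TRUE`
#' instead re-computes the hull after each removal. If fewer than four
#' points would remain (the minimum for a 3D hull), the original set is
#' returned unchanged, as is any set whose hull is degenerate.
#'
#' @param points numeric matrix with 3 columns (soma coordinates, um).
#' @param sequential logical; re-compute the hull after each removal.
#' @return list with `points` (retained rows), `removed` (row indices of
#'   removed outliers), `volume_full`, `volume_trimmed` and `note`.
#' @export
remove_hull_outliers <- function(points, sequential = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  unchanged <- function(note) {
    list(points = points, removed = integer(0),
         volume_full = hull_volume(points),
         volume_trimmed = hull_volume(points), note = note)
  }
  if (n < 5L) {
    return(unchanged("kept all points: removal would leave fewer than 4"))
  }
  full <- convex_hull_3d(points)
  if (full$degenerate) {
    return(unchanged("kept all points: degenerate hull"))
  }
  if (sequential) {
    keep <- seq_len(n)
    removed <- integer(0)
    i <- 1L
    while (i <= length(keep)) {
      if (length(keep) <= 4L) break
      v <- hull_volume(points[keep, , drop = FALSE])
      v_wo <- hull_volume(points[keep[-i], , drop = FALSE])
      if (abs(v - v_wo) > v / length(keep)) {
        removed <- c(removed, keep[i])
        keep <- keep[-i]
      } else {
        i <- i + 1L
      }
    }
    trimmed <- points[keep, , drop = FALSE]
    return(list(points = trimmed, removed = removed,
                volume_full = full$volume,
                volume_trimmed = hull_volume(trimmed), note = NULL))
  }
  v_wo <- vapply(seq_len(n), function(i) {
    hull_volume(points[-i, , drop = FALSE])
  }, numeric(1))
  flagged <- which(abs(full$volume - v_wo) > full$volume / n)
  if (n - length(flagged) < 4L) {
    return(unchanged(
      "kept all points: outlier removal would leave fewer than 4"))
  }
  trimmed <- if (length(flagged)) points[-flagged, , drop = FALSE] else
    points
  list(points = trimmed, removed = flagged, volume_full = full$volume,
       volume_trimmed = hull_volume(trimmed), note = NULL)
}

#' Overlap of two soma convex hulls
#'
#' Computes the intersection of the two convex hulls exactly, as the
#' bounded intersection of both hulls' facet halfspaces (the intersection
#' of convex polytopes is itself a convex polytope whose vertices lie on
#' triples of facet planes). The similarity between the two territories is
#' the ratio of the overlap volume to the union volume,
#' `V(a and b) / (V(a) + V(b) - V(a and b))`, a symmetric quantity in
#' \[0, 1\]. An empty or lower-dimensional intersection is reported as
#' ratio 0 with `empty_intersection = TRUE` rather than as an error.
#'
#' @param a,b numeric matrices with 3 columns; each must have a
#'   non-degenerate 3D hull.
#' @return list with `v_a`, `v_b`, `v_intersection`, `v_union`, `ratio`,
#'   `empty_intersection`.
#' @export
hull_overlap <- function(a, b) {
  ha <- convex_hull_3d(a)
  hb <- convex_hull_3d(b)
  if (ha$degenerate || hb$degenerate) {
    stop("degenerate hull: point set does not span 3 dimensions")
  }
  tol <- 1e-9 * max(1, max(abs(a)), max(abs(b)))
  normals <- rbind(ha$normals, hb$normals)
  offsets <- c(ha$offsets, hb$offsets)
  key <- paste(round(normals[, 1L], 9L), round(normals[, 2L], 9L),
               round(normals[, 3L], 9L), signif(offsets, 12L))
  dup <- duplicated(key)
  normals <- normals[!dup, , drop = FALSE]
  offsets <- offsets[!dup]
  verts <- halfspace_vertices(normals, offsets, tol)
  v_int <- 0
  empty <- TRUE
  if (nrow(verts) >= 4L) {
    v <- polytope_volume(normals, offsets, verts, tol)
    if (v > tol * max(ha$volume, hb$volume)) {
      v_int <- v
      empty <- FALSE
    }
  }
  v_union <- ha$volume + hb$volume - v_int
  list(v_a = ha$volume, v_b = hb$volume, v_intersection = v_int,
       v_union = v_union, ratio = v_int / v_union,
       empty_intersection = empty)
}

#' Layer composition of a soma set
#'
#' @param layers character vector of per-soma layer labels (e.g. from a
#'   soma table's `layer` column). `NA` entries are an error.
#' @return data frame with columns `layer`, `count`, `fraction`
#'   (fractions sum to one).
#' @export
layer_composition <- function(layers) {
  if (!length(layers)) stop("no layer labels")
  unlabeled <- which(is.na(layers) | layers == "")
  if (length(unlabeled)) {
    stop("unlabeled soma(s) at position(s): ",
         paste(utils::head(unlabeled, 10L), collapse = ", "))
  }
  tab <- table(layers)
  data.frame(layer = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Soma topography report across classes
#'
#' Runs outlier removal and pairwise hull-overlap analysis for every
#' class in a soma table, plus per-class layer composition when layer
#' labels are present.
#'
#' @param somata data frame with columns `class`, `x`, `y`, `z` and
#'   optionally `layer` (see [read_soma_csv()]).
#' @param remove_outliers logical; apply [remove_hull_outliers()] per
#'   class first.
#' @param min_class_size classes with fewer somata are skipped (a 3D hull
#'   needs at least 4 points).
#' @return object of class `hull_report`: list with `classes` (per-class
#'   list: `n`, `removed`, `volume`), `overlaps` (data frame `class_a`,
#'   `class_b`, `v_intersection`, `v_union`, `ratio`,
#'   `empty_intersection`), `layers` (data frame or `NULL`), `skipped`.
#' @export
soma_hull_report <- function(somata, remove_outliers = TRUE,
                             min_class_size = 4L) {
  if (!all(c("class", "x", "y", "z") %in% names(somata))) {
    stop("somata needs columns class, x, y, z")
  }
  classes <- sort(unique(as.character(somata$class)))
  per_class <- list()
  skipped <- character(0)
  for (cl in classes) {
    pts <- as.matrix(somata[somata$class == cl, c("x", "y", "z")])
    if (nrow(pts) < min_class_size ||
        convex_hull_3d(pts)$degenerate) {
      skipped <- c(skipped, cl)
      next
    }
    trim <- if (remove_outliers) remove_hull_outliers(pts) else
      list(points = pts, removed = integer(0),
           volume_trimmed = hull_volume(pts))
    per_class[[cl]] <- list(n = nrow(pts), removed = trim$removed,
                            volume = trim$volume_trimmed,
                            points = trim$points)
  }
  kept <- names(per_class)
  overlaps <- NULL
  if (length(kept) >= 2L) {
    pairs <- utils::combn(kept, 2L)
    overlaps <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      ov <- hull_overlap(per_class[[pairs[1L, j]]]$points,
                         per_class[[pairs[2L, j]]]$points)
      data.frame(class_a = pairs[1L, j], class_b = pairs[2L, j],
                 v_intersection = ov$v_intersection, v_union = ov$v_union,
                 ratio = ov$ratio,
                 empty_intersection = ov$empty_intersection,
                 stringsAsFactors = FALSE)
    }))
  }
  layers <- NULL
  if ("layer" %in% names(somata)) {
    layers <- do.call(rbind, lapply(classes, function(cl) {
      lc <- layer_composition(somata$layer[somata$class == cl])
      cbind(class = cl, lc, stringsAsFactors = FALSE)
    }))
  }
  structure(list(classes = per_class, overlaps = overlaps,
                 layers = layers, skipped = skipped),
            class = "hull_report")
}

#' @export
print.hull_report <- function(x, ...) {
  cat("<hull_report> ", length(x$classes), " class hull(s)\n", sep = "")
  if (!is.null(x$overlaps)) {
    print(x$overlaps, digits = 4)
  }
  if (length(x$skipped)) {
    cat("skipped (too few somata):", paste(x$skipped, collapse = ", "),
        "\n")
  }
  invisible(x)
}
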