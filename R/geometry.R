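# 3D convex hull and convex polytope intersection.
#
# An incremental (beneath-beyond) hull is sufficient here: soma clouds
# hold tens of points. Points coplanar with a facet of the growing hull
# are treated as visible when the point is strictly outside, so inputs in
# non-general position (cube corners, polytope vertex sets with coplanar
# faces) are handled without perturbing coordinates.

hull_eps <- function(pts) 1e-9 * max(1, max(abs(pts)))

#' Convex hull of a 3D point set
#'
#' @param pts numeric matrix with 3 columns (one point per row).
#' @return object of class `hull3d`: list with `faces` (t x 3 matrix of
#'   row indices into `pts`, outward-oriented triangles), `normals`
#'   (t x 3, unit outward normals), `offsets` (facet plane offsets, the
#'   hull is the set `normals %*% x <= offsets`), `vertices` (indices of
#'   hull vertices), `volume`, `interior` (a strictly interior point) and
#'   `degenerate` (`TRUE` when the points do not span 3 dimensions; then
#'   `volume` is 0 and the facet fields are `NULL`).
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3L) stop("pts must have 3 columns")
  if (any(!is.finite(pts))) stop("pts must be finite")
  n <- nrow(pts)
  eps <- hull_eps(pts)
  degenerate <- structure(
    list(faces = NULL, normals = NULL, offsets = NULL,
         vertices = seq_len(n), volume = 0, interior = NULL,
         degenerate = TRUE),
    class = "hull3d"
  )
  if (n < 4L) return(degenerate)

  # initial simplex: spread-out extremes
  i1 <- which.min(pts[, 1L])
  d1 <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) <= eps) return(degenerate)
  u <- pts[i2, ] - pts[i1, ]
  u <- u / sqrt(sum(u^2))
  rel <- sweep(pts, 2L, pts[i1, ])
  proj <- rel %*% u
  perp2 <- rowSums(rel^2) - proj^2
  i3 <- which.max(perp2)
  if (sqrt(max(perp2[i3], 0)) <= eps) return(degenerate)
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  hdist <- rel %*% nrm
  i4 <- which.max(abs(hdist))
  if (abs(hdist[i4]) <= eps) return(degenerate)

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4),
                 c(i2, i3, i4))
  faces <- t(apply(faces, 1L, orient_face, pts = pts,
                   interior = interior))
  planes <- face_planes(faces, pts)

  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    dists <- planes$normals %*% pts[p, ] - planes$offsets
    if (max(dists) <= eps) next
    visible <- as.vector(dists > -eps)
    # horizon: edges of visible facets shared with exactly one of them
    vis_faces <- faces[visible, , drop = FALSE]
    edges <- rbind(vis_faces[, c(1L, 2L)], vis_faces[, c(2L, 3L)],
                   vis_faces[, c(1L, 3L)])
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), ,
                     drop = FALSE]
    if (!nrow(horizon)) next
    new_faces <- cbind(horizon, p)
    new_faces <- t(apply(new_faces, 1L, orient_face, pts = pts,
                         interior = interior))
    faces <- rbind(faces[!visible, , drop = FALSE], new_faces)
    planes <- face_planes(faces, pts)
  }

  a <- pts[faces[, 1L], , drop = FALSE]
  b <- pts[faces[, 2L], , drop = FALSE]
  ce <- pts[faces[, 3L], , drop = FALSE]
  o <- matrix(interior, nrow(faces), 3L, byrow = TRUE)
  vol <- sum(triple_product(a - o, b - o, ce - o)) / 6
  structure(
    list(faces = faces, normals = planes$normals,
         offsets = as.vector(planes$offsets),
         vertices = sort(unique(as.vector(faces))),
         volume = vol, interior = interior, degenerate = FALSE),
    class = "hull3d"
  )
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

triple_product <- function(a, b, ce) {
  cx <- b[, 2L] * ce[, 3L] - b[, 3L] * ce[, 2L]
  cy <- b[, 3L] * ce[, 1L] - b[, 1L] * ce[, 3L]
  cz <- b[, 1L] * ce[, 2L] - b[, 2L] * ce[, 1L]
  a[, 1L] * cx + a[, 2L] * cy + a[, 3L] * cz
}

orient_face <- function(face, pts, interior) {
  nrm <- cross3(pts[face[2L], ] - pts[face[1L], ],
                pts[face[3L], ] - pts[face[1L], ])
  if (sum(nrm * (interior - pts[face[1L], ])) > 0) {
    face <- face[c(1L, 3L, 2L)]
  }
  face
}

face_planes <- function(faces, pts) {
  normals <- t(apply(faces, 1L, function(f) {
    nrm <- cross3(pts[f[2L], ] - pts[f[1L], ], pts[f[3L], ] - pts[f[1L], ])
    nrm / sqrt(sum(nrm^2))
  }))
  offsets <- rowSums(normals * pts[faces[, 1L], , drop = FALSE])
  list(normals = normals, offsets = offsets)
}

#' Convex hull volume
#'
#' @inheritParams convex_hull_3d
#' @return hull volume (0 for degenerate point sets).
#' @export
hull_volume <- function(pts) convex_hull_3d(pts)$volume

#' Test whether points lie inside a convex hull
#'
#' @param hull a `hull3d` from [convex_hull_3d()].
#' @param pts points to test (matrix with 3 columns).
#' @param tol boundary tolerance.
#' @return logical vector.
#' @export
hull_contains <- function(hull, pts, tol = 1e-9) {
  if (hull$degenerate) stop("degenerate hull")
  pts <- as.matrix(pts)
  d <- pts %*% t(hull$normals) -
    matrix(hull$offsets, nrow(pts), length(hull$offsets), byrow = TRUE)
  apply(d <= tol, 1L, all)
}

# Enumerate the vertices of the polytope {x : N x <= d} from all triples
# of bounding planes; returns a (possibly empty) matrix of vertices.
halfspace_vertices <- function(normals, offsets, tol) {
  m <- nrow(normals)
  if (m < 3L) return(matrix(numeric(0), 0L, 3L))
  idx <- t(utils::combn(m, 3L))
  n1 <- normals[idx[, 1L], , drop = FALSE]
  n2 <- normals[idx[, 2L], , drop = FALSE]
  n3 <- normals[idx[, 3L], , drop = FALSE]
  d1 <- offsets[idx[, 1L]]
  d2 <- offsets[idx[, 2L]]
  d3 <- offsets[idx[, 3L]]
  c23 <- cbind(n2[, 2L] * n3[, 3L] - n2[, 3L] * n3[, 2L],
               n2[, 3L] * n3[, 1L] - n2[, 1L] * n3[, 3L],
               n2[, 1L] * n3[, 2L] - n2[, 2L] * n3[, 1L])
  c31 <- cbind(n3[, 2L] * n1[, 3L] - n3[, 3L] * n1[, 2L],
               n3[, 3L] * n1[, 1L] - n3[, 1L] * n1[, 3L],
               n3[, 1L] * n1[, 2L] - n3[, 2L] * n1[, 1L])
  c12 <- cbind(n1[, 2L] * n2[, 3L] - n1[, 3L] * n2[, 2L],
               n1[, 3L] * n2[, 1L] - n1[, 1L] * n2[, 3L],
               n1[, 1L] * n2[, 2L] - n1[, 2L] * n2[, 1L])
  det <- rowSums(n1 * c23)
  ok <- abs(det) > 1e-12
  if (!any(ok)) return(matrix(numeric(0), 0L, 3L))
  verts <- (c23[ok, , drop = FALSE] * d1[ok] +
              c31[ok, , drop = FALSE] * d2[ok] +
              c12[ok, , drop = FALSE] * d3[ok]) / det[ok]
  # keep vertices satisfying every halfspace (chunked to bound memory)
  keep <- logical(nrow(verts))
  step <- 50000L
  for (start in seq(1L, nrow(verts), by = step)) {
    rows <- start:min(start + step - 1L, nrow(verts))
    slack <- verts[rows, , drop = FALSE] %*% t(normals) -
      matrix(offsets, length(rows), m, byrow = TRUE)
    keep[rows] <- apply(slack <= tol, 1L, all)
  }
  verts <- verts[keep, , drop = FALSE]
  if (nrow(verts)) {
    key <- apply(signif(verts, 10), 1L, paste, collapse = ",")
    verts <- verts[!duplicated(key), , drop = FALSE]
  }
  verts
}

# Volume of the bounded polytope {x : N x <= d} given its vertex set:
# sum of pyramids from an interior point over the facet polygons. Exact
# (up to round-off) and independent of facet or vertex ordering.
polytope_volume <- function(normals, offsets, verts, tol) {
  if (nrow(verts) < 4L) return(0)
  o <- colMeans(verts)
  total <- 0
  for (f in seq_len(nrow(normals))) {
    nrm <- normals[f, ]
    on_plane <- abs(verts %*% nrm - offsets[f]) <= 10 * tol
    if (sum(on_plane) < 3L) next
    face <- verts[on_plane, , drop = FALSE]
    centroid <- colMeans(face)
    # orthonormal in-plane basis
    e <- diag(3L)[, which.min(abs(nrm))]
    u <- cross3(nrm, e)
    u <- u / sqrt(sum(u^2))
    w <- cross3(nrm, u)
    rel <- sweep(face, 2L, centroid)
    ang <- atan2(rel %*% w, rel %*% u)
    ordv <- face[order(ang), , drop = FALSE]
    a2 <- ordv %*% u
    b2 <- ordv %*% w
    area <- abs(sum(a2 * (b2[c(2:length(b2), 1L)] -
                            b2[c(length(b2), 1:(length(b2) - 1L))]))) / 2
    height <- offsets[f] - sum(nrm * o)
    total <- total + area * height / 3
  }
  total
}
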