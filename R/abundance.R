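#' Bi-normalize a class projection-weight matrix
#'
#' Sequential normalization of the regions-by-classes weight matrix used
#' in abundance deconvolution, first by axonal length and then by invaded
#' region: (1) each row is divided by its sum; (2) every cell is scaled by
#' `k_classes / m_regions`, so the grand total equals the number of
#' classes; (3) each column is divided by its sum. Intermediate totals are
#' recorded in the `"totals"` attribute.
#'
#' @param raw_A non-negative matrix with regions as rows and classes as
#'   columns; no all-zero row or column.
#' @return the step-3 matrix (each column sums to one) with attribute
#'   `totals` = named vector of grand totals after each step.
#' @export
binormalize <- function(raw_A) {
  if (!is.matrix(raw_A) || !is.numeric(raw_A) || any(raw_A < 0)) {
    stop("raw_A must be a non-negative numeric matrix")
  }
  zr <- which(rowSums(raw_A) == 0)
  if (length(zr)) {
    stop("all-zero row in A: ",
         rownames(raw_A)[zr[1L]] %||% zr[1L])
  }
  zc <- which(colSums(raw_A) == 0)
  if (length(zc)) {
    stop("all-zero column in A: ",
         colnames(raw_A)[zc[1L]] %||% zc[1L])
  }
  m <- nrow(raw_A)
  k <- ncol(raw_A)
  step1 <- raw_A / rowSums(raw_A)
  step2 <- step1 * (k / m)
  step3 <- sweep(step2, 2L, colSums(step2), "/")
  attr(step3, "totals") <- c(raw = sum(raw_A), after_row_norm = sum(step1),
                             after_rescale = sum(step2),
                             after_col_norm = sum(step3))
  step3
}

#' Assemble the abundance deconvolution problem
#'
#' Builds the non-negative least squares problem `A x = b` that matches
#' per-class single-neuron projection patterns against regional
#' anterograde tracing strengths. Rows of `A` are the regions shared
#' between the count matrix and the regional table; column c holds the
#' summed counts of class c's neurons per region, bi-normalized with
#' [binormalize()]. `b` is the per-region projection weight (mean tracing
#' volume times mean density), normalized to sum one.
#'
#' Hemisphere-split matrix columns are pooled by parcel before matching,
#' since regional tracing strengths are not hemisphere-resolved.
#'
#' @param matrix neuron-by-region count matrix.
#' @param assignment data frame `neuron_id`, `class`.
#' @param regional data frame with columns `region` and either `weight`
#'   or both `mean_volume` and `mean_density` (see [read_regional_csv()]).
#' @return object of class `abundance_problem`: list with `A`
#'   (bi-normalized), `raw_A`, `b`, `regions`, `classes`.
#' @export
abundance_problem <- function(matrix, assignment, regional) {
  validate_projection_matrix(matrix)
  assignment <- validate_assignment(assignment, rownames(matrix))
  if (!"weight" %in% names(regional)) {
    if (!all(c("mean_volume", "mean_density") %in% names(regional))) {
      stop("regional table needs a 'weight' column or both 'mean_volume' ",
           "and 'mean_density'")
    }
    regional$weight <- regional$mean_volume * regional$mean_density
  }
  # pool hemisphere-split columns to bare parcels
  parcels <- parse_region_labels(colnames(matrix))$parcel_id
  pooled <- t(rowsum(t(matrix), group = parcels))
  shared <- intersect(colnames(pooled), regional$region)
  if (length(shared) < 2L) {
    stop("need at least two regions shared between the count matrix and ",
         "the regional table (got ", length(shared), ")")
  }
  classes <- sort(unique(assignment$class))
  raw_A <- vapply(classes, function(cl) {
    members <- assignment$neuron_id[assignment$class == cl]
    colSums(pooled[members, shared, drop = FALSE])
  }, numeric(length(shared)))
  raw_A <- matrix(raw_A, nrow = length(shared),
                  dimnames = list(shared, classes))
  keep <- rowSums(raw_A) > 0
  if (!all(keep)) raw_A <- raw_A[keep, , drop = FALSE]
  b <- regional$weight[match(rownames(raw_A), regional$region)]
  if (sum(b) <= 0) stop("regional weights sum to zero over shared regions")
  b <- b / sum(b)
  structure(
    list(A = binormalize(raw_A), raw_A = raw_A, b = b,
         regions = rownames(raw_A), classes = classes),
    class = "abundance_problem"
  )
}

#' Solve the non-negative least squares abundance problem
#'
#' Finds `x >= 0` minimizing the Euclidean norm of `A x - b` (Lawson -
#' Hanson active-set algorithm via `pracma::lsqnonneg`). The squared
#' residual norm is reported as a proxy for the uncertainty of the
#' deconvolution; `fractions` renormalizes `x` to sum one, the scale on
#' which class abundances are quoted.
#'
#' @param problem an `abundance_problem`, or a matrix `A` (then `b` must
#'   be given).
#' @param b regional weight vector (only when `problem` is a matrix).
#' @return object of class `abundance_estimate`: list with `x` (raw
#'   solution), `fractions` (x normalized to sum one), `residual_sq`
#'   (squared Euclidean residual norm) and `classes`.
#' @export
nnls_solve <- function(problem, b = NULL) {
  if (inherits(problem, "abundance_problem")) {
    A <- problem$A
    b <- problem$b
    classes <- problem$classes
  } else {
    A <- as.matrix(problem)
    if (is.null(b)) stop("b is required when A is given directly")
    classes <- colnames(A) %||% paste0("class", seq_len(ncol(A)))
  }
  if (nrow(A) != length(b)) stop("dimensions of A and b disagree")
  fit <- pracma::lsqnonneg(A, as.numeric(b))
  x <- pmax(fit$x, 0)
  names(x) <- classes
  residual_sq <- sum((A %*% x - b)^2)
  fractions <- if (sum(x) > 0) x / sum(x) else x
  structure(
    list(x = x, fractions = fractions, residual_sq = residual_sq,
         classes = classes),
    class = "abundance_estimate"
  )
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat("<abundance_estimate> class fractions:\n")
  print(round(100 * x$fractions, 1))
  cat("squared residual norm: ", format(x$residual_sq, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Per-class shares of a region's afferents
#'
#' Combines estimated class abundances with per-class projection profiles
#' to apportion a target region's afferent input among classes: the share
#' of class c is proportional to `fraction(c) * profile(c, region)`,
#' normalized over classes.
#'
#' @param class_fractions named vector of class abundance fractions (e.g.
#'   `fractions` from [nnls_solve()]).
#' @param profiles classes-by-regions profile matrix from
#'   [class_profiles()].
#' @param region region label (a column of `profiles`).
#' @return named vector of shares summing to one.
#' @export
afferent_composition <- function(class_fractions, profiles, region) {
  if (!region %in% colnames(profiles)) {
    stop("region '", region, "' not found in profiles")
  }
  classes <- rownames(profiles)
  if (!all(classes %in% names(class_fractions))) {
    stop("class_fractions and profiles disagree on the class set")
  }
  w <- class_fractions[classes] * profiles[, region]
  total <- sum(w)
  if (total <= 0) {
    stop("undefined composition: region '", region,
         "' receives no projection from any class")
  }
  w / total
}
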