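#' Per-neuron median path distances to each invaded region
#'
#' For every neuron and every region its axon invades, the cable
#' (path) distance from the soma to each axonal point in the region is
#' measured along the reconstruction tree, and summarized by the median.
#' Neurons with no axonal point in a region contribute no record for it.
#' With `split_hemispheres`, ipsilateral and contralateral territories of
#' a parcel are kept as separate regions (contralateral targets are
#' systematically farther).
#'
#' @param neurons list of [neuron_reconstruction()] objects.
#' @param assignment data frame `neuron_id`, `class`; neurons absent from
#'   the assignment are skipped.
#' @param midline,axis,split_hemispheres hemisphere handling as in
#'   [tabulate_projections()].
#' @return data frame with one row per (neuron, invaded region):
#'   `neuron_id`, `class`, `region`, `n_points`, `median_distance` (um).
#' @export
path_distance_records <- function(neurons, assignment, midline = NULL,
                                  split_hemispheres = FALSE, axis = "z") {
  assignment <- validate_assignment(assignment)
  if (split_hemispheres) stopifnot_scalar_number(midline, "midline")
  recs <- lapply(neurons, function(nr) {
    cls <- assignment$class[match(nr$neuron_id, assignment$neuron_id)]
    if (is.na(cls)) return(NULL)
    nodes <- nr$nodes
    dist <- path_distances(nr)
    sel <- nodes$structure == "axon" & nodes$parcel_id != "unassigned"
    if (!any(sel)) return(NULL)
    if (split_hemispheres) {
      soma_side <- sign(soma_node(nr)[[axis]] - midline)
      if (soma_side == 0) soma_side <- 1
      node_side <- sign(nodes[[axis]][sel] - midline)
      node_side[node_side == 0] <- soma_side
      region <- make_region_label(
        nodes$parcel_id[sel],
        ifelse(node_side == soma_side, "ipsi", "contra"))
    } else {
      region <- nodes$parcel_id[sel]
    }
    med <- tapply(dist[sel], region, stats::median)
    npt <- tapply(dist[sel], region, length)
    data.frame(neuron_id = nr$neuron_id, class = cls,
               region = names(med), n_points = as.integer(npt),
               median_distance = as.numeric(med),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no path-distance records produced")
  rownames(out) <- NULL
  out
}

# Two-sample rank-sum (Mann-Whitney) comparison of per-neuron medians.
# Exact null when the combined sample is small and tie-free, normal
# approximation with tie correction otherwise.
ranksum_compare <- function(x, y, exact_max = 20L) {
  if (length(unique(c(x, y))) == 1L) {
    # all observations tied: no evidence of a shift in either direction
    return(list(statistic = length(x) * length(y) / 2, p = 1,
                direction = "similar", median_a = x[1L],
                median_b = y[1L]))
  }
  use_exact <- (length(x) + length(y)) <= exact_max &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  diff_med <- stats::median(x) - stats::median(y)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       direction = if (diff_med < 0) "shorter" else if (diff_med > 0)
         "longer" else "similar",
       median_a = stats::median(x), median_b = stats::median(y))
}

rank_test_table <- function(records, group_col, fixed_col, alpha,
                            min_records) {
  groups <- sort(unique(records[[group_col]]))
  usable <- groups[vapply(groups, function(g) {
    sum(records[[group_col]] == g) >= min_records
  }, logical(1))]
  excluded <- setdiff(groups, usable)
  if (length(usable) < 2L) {
    out <- data.frame()
    attr(out, "excluded") <- excluded
    return(out)
  }
  pairs <- utils::combn(usable, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ga <- pairs[1L, j]
    gb <- pairs[2L, j]
    x <- records$median_distance[records[[group_col]] == ga]
    y <- records$median_distance[records[[group_col]] == gb]
    rs <- ranksum_compare(x, y)
    data.frame(a = ga, b = gb, n_a = length(x), n_b = length(y),
               median_a = rs$median_a, median_b = rs$median_b,
               statistic = rs$statistic, p_raw = rs$p,
               direction = rs$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- fdr_adjust(out$p_raw)
  out$significant <- out$q_fdr < alpha
  names(out)[1:2] <- paste0(fixed_col, c("_a", "_b"))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Divergence analysis: one class, many targets
#'
#' Within one projection class, compares the per-neuron median path
#' distances between every pair of target regions with a two-sample
#' rank-sum test, correcting the family of pairwise comparisons with
#' Benjamini-Hochberg FDR at `alpha`. Ipsilateral and contralateral
#' regions are distinct targets and are only compared within the same
#' side. The reported `direction` is that of the first target relative to
#' the second (`"shorter"` means target a is reached by shorter paths).
#'
#' @param records data frame from [path_distance_records()].
#' @param class_label the class analyzed.
#' @param alpha FDR level.
#' @param min_records targets with fewer per-neuron medians are excluded
#'   (reported in the `"excluded"` attribute).
#' @return data frame with one row per target pair: `region_a`,
#'   `region_b`, sample sizes, medians, `statistic`, `p_raw`,
#'   `direction`, `q_fdr`, `significant`.
#' @export
divergence_test <- function(records, class_label, alpha = 0.05,
                            min_records = 2L) {
  sub <- records[records$class == class_label, , drop = FALSE]
  if (!nrow(sub)) stop("no records for class '", class_label, "'")
  sides <- parse_region_labels(sub$region)$side
  out <- NULL
  excluded <- character(0)
  for (s in unique(sides)) {
    tab <- rank_test_table(sub[sides == s, , drop = FALSE],
                           group_col = "region", fixed_col = "region",
                           alpha = alpha, min_records = min_records)
    excluded <- c(excluded, attr(tab, "excluded"))
    if (nrow(tab)) out <- rbind(out, tab)
  }
  if (is.null(out)) {
    out <- data.frame()
    message("divergence test for class '", class_label,
            "': fewer than two testable targets")
  } else if (length(unique(sides)) > 1L) {
    # FDR family = all pairs tested for this class (both sides together)
    out$q_fdr <- fdr_adjust(out$p_raw)
    out$significant <- out$q_fdr < alpha
  }
  attr(out, "excluded") <- unique(excluded)
  out
}

#' Convergence analysis: many classes, one target
#'
#' For one target region, compares the per-neuron median path distances
#' between every pair of classes that reach it, with rank-sum tests and
#' Benjamini-Hochberg FDR across the class pairs.
#'
#' @param records data frame from [path_distance_records()].
#' @param region the target region analyzed.
#' @inheritParams divergence_test
#' @return data frame with one row per class pair: `class_a`, `class_b`,
#'   sample sizes, medians, `statistic`, `p_raw`, `direction`, `q_fdr`,
#'   `significant`.
#' @export
convergence_test <- function(records, region, alpha = 0.05,
                             min_records = 2L) {
  sub <- records[records$region == region, , drop = FALSE]
  if (!nrow(sub)) stop("no records for region '", region, "'")
  out <- rank_test_table(sub, group_col = "class", fixed_col = "class",
                         alpha = alpha, min_records = min_records)
  if (!nrow(out)) {
    message("convergence test for region '", region,
            "': fewer than two classes reach it with enough neurons")
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; significance at level alpha is then simply
#' `q < alpha`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return vector of q-values (same length and order).
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
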