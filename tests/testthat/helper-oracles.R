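# Independent brute-force oracles, deliberately naive implementations.

# UPGMA by direct definition: average of all cross-pair ORIGINAL distances
upgma_heights_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# NNLS by exhaustive enumeration of supports (feasible unconstrained LS)
nnls_oracle <- function(A, b) {
  k <- ncol(A)
  best_x <- rep(0, k)
  best_res <- sum(b^2)
  for (size in seq_len(k)) {
    subsets <- utils::combn(k, size, simplify = FALSE)
    for (s in subsets) {
      As <- A[, s, drop = FALSE]
      coef <- tryCatch(qr.coef(qr(As), b), error = function(e) NULL)
      if (is.null(coef) || anyNA(coef) || any(coef < -1e-12)) next
      x <- rep(0, k)
      x[s] <- pmax(coef, 0)
      res <- sum((A %*% x - b)^2)
      if (res < best_res) {
        best_res <- res
        best_x <- x
      }
    }
  }
  list(x = best_x, residual_sq = best_res)
}

# Benjamini-Hochberg by its step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  for (i in (m - 1):1) {
    if (m < 2) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# all 2x2 non-negative integer tables with the given margins
enumerate_tables_2x2 <- function(row_sums, col_sums) {
  out <- list()
  for (a in 0:min(row_sums[1], col_sums[1])) {
    b <- row_sums[1] - a
    ca <- col_sums[1] - a
    cb <- row_sums[2] - ca
    if (b >= 0 && ca >= 0 && cb >= 0 && b + cb == col_sums[2]) {
      out[[length(out) + 1L]] <- matrix(c(a, ca, b, cb), 2, 2)
    }
  }
  out
}

# exact two-sided rank-sum p-value by enumeration of all group splits
ranksum_p_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  center <- nx * length(y) / 2
  splits <- utils::combn(length(pooled), nx, simplify = FALSE)
  u_all <- vapply(splits, function(s) {
    sum(r[s]) - nx * (nx + 1) / 2
  }, numeric(1))
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-12)
}

# root-to-node path length by explicit parent-chain walking
path_oracle <- function(neuron, node_id) {
  nodes <- neuron$nodes
  total <- 0
  cur <- which(nodes$node_id == node_id)
  while (!is.na(nodes$parent_id[cur])) {
    par <- which(nodes$node_id == nodes$parent_id[cur])
    total <- total + sqrt(sum((nodes[cur, c("x", "y", "z")] -
                                 nodes[par, c("x", "y", "z")])^2))
    cur <- par
  }
  total
}
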