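test_that("path distances accumulate segment lengths along the tree", {
  # 3-4-5 construction: path length 7 exceeds the Euclidean 5
  nodes <- make_nodes(1:3, c(0, 3, 3), c(0, 0, 4), 0, c(NA, 1, 2),
                      c("soma", "axon", "axon"), "P")
  nr <- neuron_reconstruction("n1", nodes)
  expect_equal(path_distance(nr, 1), 0)
  expect_equal(path_distance(nr, 3), 7)
  expect_error(path_distance(nr, 9), "does not exist")
})

test_that("path distances match the explicit root-path oracle on a branched tree", {
  nodes <- make_nodes(1:6,
                      c(0, 1, 3, 3, 0, -2), c(0, 0, 0, 2, 1, 1), 0,
                      c(NA, 1, 2, 2, 1, 5),
                      c("soma", rep("axon", 5)), "P")
  nr <- neuron_reconstruction("branchy", nodes)
  pd <- path_distances(nr)
  for (id in nr$nodes$node_id) {
    expect_equal(unname(pd[as.character(id)]), path_oracle(nr, id),
                 tolerance = 1e-12)
  }
})

test_that("path distance dominates Euclidean distance on synthetic trees", {
  g <- generate_matrix(2, 6, 6, size_meanlog = log(30), seed = 801)
  morph <- generate_morphologies(pmin(g$matrix, 6), g$assignment,
                                 seed = 802)
  for (nr in morph$neurons) {
    pd <- path_distances(nr)
    soma <- as.numeric(nr$nodes[1, c("x", "y", "z")])
    eu <- sqrt(rowSums(sweep(as.matrix(nr$nodes[, c("x", "y", "z")]),
                             2, soma)^2))
    expect_true(all(pd >= eu - 1e-9))
  }
})

test_that("per-neuron records take the median over in-region points", {
  # points at path distances 1, 2, 9 in region P -> median 2
  nodes <- make_nodes(1:4, c(0, 1, 2, 9), 0, 0, c(NA, 1, 2, 3),
                      c("soma", rep("axon", 3)), c("SRC", "P", "P", "P"))
  nr <- neuron_reconstruction("n1", nodes)
  assignment <- data.frame(neuron_id = "n1", class = "K1")
  recs <- path_distance_records(list(nr), assignment)
  expect_equal(recs$median_distance[recs$region == "P"], 2)
  expect_equal(recs$n_points[recs$region == "P"], 3L)
  expect_false("Q" %in% recs$region)
})

test_that("records match a hand-enumerated two-neuron table", {
  n1 <- chain_neuron("n1", c("A", "A", "B"), step = 10)
  n2 <- chain_neuron("n2", c("B", "B"), step = 5)
  assignment <- data.frame(neuron_id = c("n1", "n2"),
                           class = c("K1", "K2"))
  recs <- path_distance_records(list(n1, n2), assignment)
  recs <- recs[order(recs$neuron_id, recs$region), ]
  # n1: A at 10, 20 (median 15); B at 30. n2: B at 5, 10 (median 7.5)
  expect_equal(recs$median_distance, c(15, 30, 7.5))
  expect_equal(recs$region, c("A", "B", "B"))
})

test_that("divergence testing flags separated targets and not identical ones", {
  mk <- function(region, med, cls = "K1") {
    data.frame(neuron_id = paste0(region, seq_along(med)), class = cls,
               region = region, n_points = 1L, median_distance = med)
  }
  same <- rbind(mk("A", c(3, 1, 4, 2, 5)), mk("B", c(3, 1, 4, 2, 5)))
  res_same <- divergence_test(same, "K1")
  expect_equal(res_same$p_raw, 1)
  expect_false(res_same$significant)

  far <- rbind(mk("A", 1:5), mk("B", 101:105))
  res_far <- divergence_test(far, "K1")
  # complete separation at n = 5 vs 5: exact two-sided p = 2/choose(10,5)
  expect_equal(res_far$p_raw, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res_far$p_raw,
               ranksum_p_oracle(1:5, 101:105), tolerance = 1e-12)
  expect_true(res_far$significant)
  expect_identical(res_far$direction, "shorter")
})

test_that("ipsilateral and contralateral targets are never compared", {
  recs <- data.frame(
    neuron_id = rep(paste0("n", 1:4), 2), class = "K1",
    region = rep(c("A|ipsi", "A|contra"), each = 4), n_points = 1L,
    median_distance = c(1:4, 101:104))
  res <- divergence_test(recs, "K1")
  expect_equal(nrow(res), 0L)
})

test_that("convergence testing compares classes at one target with direction", {
  recs <- rbind(
    data.frame(neuron_id = paste0("a", 1:6), class = "A38",
               region = "SUB", n_points = 1L,
               median_distance = c(3000, 3100, 3050, 2990, 3020, 3060)),
    data.frame(neuron_id = paste0("b", 1:6), class = "B27",
               region = "SUB", n_points = 1L,
               median_distance = c(5000, 5100, 5050, 4990, 5020, 5060)))
  res <- convergence_test(recs, "SUB")
  expect_true(res$significant)
  # B27 paths are longer, i.e. the first-listed class A38 is "shorter"
  expect_identical(res$direction, "shorter")
  expect_true(res$median_a < res$median_b)

  solo <- recs[recs$class == "A38", ]
  expect_message(res_solo <- convergence_test(solo, "SUB"),
                 "fewer than two classes")
  expect_equal(nrow(res_solo), 0L)
})

test_that("reported directions always match the sign of the median difference", {
  set.seed(31)
  for (i in 1:5) {
    recs <- rbind(
      data.frame(neuron_id = paste0("a", 1:8), class = "K1",
                 region = "R", n_points = 1L,
                 median_distance = rnorm(8, 3000, 400)),
      data.frame(neuron_id = paste0("b", 1:8), class = "K2",
                 region = "R", n_points = 1L,
                 median_distance = rnorm(8, 3000 + 300 * (i %% 3 - 1),
                                         400)))
    res <- convergence_test(recs, "R")
    expected <- if (res$median_a < res$median_b) "shorter" else
      if (res$median_a > res$median_b) "longer" else "similar"
    expect_identical(res$direction, expected)
  }
})

test_that("BH adjustment matches its definition", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(32)
  p <- runif(20)
  expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the rank test holds its size under the null", {
  set.seed(33)
  rejections <- vapply(1:300, function(i) {
    x <- rnorm(10)
    y <- rnorm(10)
    axonclass:::ranksum_compare(x, y)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})
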