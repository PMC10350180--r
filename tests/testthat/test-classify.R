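test_that("pairwise angles match closed forms", {
  m <- rbind(n1 = c(1, 0, 0), n2 = c(2, 0, 0))
  colnames(m) <- c("a", "b", "c")
  expect_equal(pairwise_angles(m)$angles, 0)

  m <- rbind(n1 = c(1, 0), n2 = c(0, 1))
  colnames(m) <- c("a", "b")
  expect_equal(pairwise_angles(m)$angles, 90)

  m <- rbind(n1 = c(3, 4), n2 = c(4, 3))
  colnames(m) <- c("a", "b")
  expect_equal(pairwise_angles(m)$angles, acos(24 / 25) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(pairwise_angles(m)$angles, 16.260204708312,
               tolerance = 1e-9)
})

test_that("angles are symmetric, bounded and scale-invariant", {
  set.seed(13)
  for (i in 1:10) {
    m <- random_count_matrix(7, 5)
    d <- pairwise_angles(m)
    expect_length(d$angles, choose(7, 2))
    expect_true(all(d$angles >= 0 & d$angles <= 180))
    scaled <- m * rep(runif(7, 0.1, 50), ncol(m))
    expect_equal(pairwise_angles(scaled)$angles, d$angles,
                 tolerance = 1e-9)
    sq <- angle_matrix(d)
    expect_equal(sq, t(sq))
  }
})

test_that("zero-norm rows are rejected by neuron name", {
  m <- rbind(good = c(1, 2), bad = c(0, 0))
  colnames(m) <- c("a", "b")
  expect_error(pairwise_angles(m), "bad")
})

test_that("the Levene gate stops on equal distributions and marks reversed variance N/A", {
  x <- c(1, 5, 9, 2, 8, 4, 6, 3)
  same <- levene_one_tailed(x, x)
  expect_identical(same$decision, "stop")
  expect_true(is.na(same$p_one_tailed))
  expect_equal(same$var_real, same$var_null)

  set.seed(2)
  rev <- levene_one_tailed(rnorm(200, sd = 1), rnorm(200, sd = 4))
  expect_true(rev$var_real < rev$var_null)
  expect_true(is.na(rev$p_one_tailed))
  expect_identical(rev$decision, "stop")
  expect_match(rev$note, "not applicable")
})

test_that("the Levene gate detects inflated real variance across seeds", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    lv <- levene_one_tailed(rnorm(500, mean = 50, sd = 9),
                            rnorm(500, mean = 50, sd = 3))
    lv$decision == "split"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the Levene statistic agrees with the mean-centered reference implementation", {
  skip_if_not_installed("car")
  set.seed(8)
  x <- rnorm(60, sd = 2)
  y <- rnorm(45, sd = 1)
  ours <- levene_one_tailed(x, y)
  ref <- car::leveneTest(c(x, y),
                         factor(rep(c("r", "n"), c(60, 45))),
                         center = mean)
  expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(ours$p_one_tailed * 2, ref[1, "Pr(>F)"],
               tolerance = 1e-10)
})

test_that("degenerate all-equal deviations stop with a diagnostic", {
  lv <- levene_one_tailed(c(1, 1, 1), c(2, 2, 2, 2))
  expect_identical(lv$decision, "stop")
  expect_match(lv$note, "degenerate")
})

test_that("average linkage reproduces forced merge orders and the UPGMA oracle", {
  d2 <- structure(list(angles = 17.5, n_items = 2L,
                       labels = c("a", "b")),
                  class = "angle_distribution")
  hc2 <- average_linkage(d2)
  expect_equal(hc2$height, 17.5)

  d3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                        c("A", "B", "C")))
  d3["A", "B"] <- d3["B", "A"] <- 10
  d3["A", "C"] <- d3["C", "A"] <- 50
  d3["B", "C"] <- d3["C", "B"] <- 50
  hc3 <- average_linkage(as.dist(d3))
  expect_equal(hc3$height, c(10, 50))
  expect_identical(sort(hc3$labels[cutree(hc3, 2) == cutree(hc3, 2)["A"]]),
                   c("A", "B"))

  set.seed(21)
  for (i in 1:5) {
    m <- random_count_matrix(6, 5)
    d <- pairwise_angles(m)
    hc <- average_linkage(d)
    expect_equal(sort(hc$height), upgma_heights_oracle(angle_matrix(d)),
                 tolerance = 1e-9)
  }
})

test_that("recursive classification recovers a planted two-class structure perfectly", {
  skip_if_not_installed("mclust")
  g <- generate_matrix(k_classes = 2, n_per_class = 15, n_regions = 10,
                       within_mass = 1, seed = 301)
  res <- classify_recursive(g$matrix, seed = 302)
  expect_equal(res$n_classes, 2L)
  ari <- mclust::adjustedRandIndex(
    res$assignment$class,
    g$assignment$class[match(res$assignment$neuron_id,
                             g$assignment$neuron_id)])
  expect_equal(ari, 1)
})

test_that("classification is deterministic given the seed", {
  g <- generate_matrix(k_classes = 2, n_per_class = 10, seed = 303)
  a <- classify_recursive(g$matrix, seed = 99)
  b <- classify_recursive(g$matrix, seed = 99)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$n_classes, b$n_classes)
})

test_that("class labels are letters ordered by decreasing size plus the size", {
  g <- generate_matrix(k_classes = 2, n_per_class = c(18, 6),
                       within_mass = 1, seed = 304)
  res <- classify_recursive(g$matrix, seed = 305)
  sizes <- sort(table(res$assignment$class), decreasing = TRUE)
  expect_identical(names(sizes), c("A18", "B6"))
})

test_that("leaves partition the neurons and respect min_testable", {
  g <- generate_matrix(k_classes = 3, n_per_class = c(12, 9, 3),
                       within_mass = 1, seed = 306)
  res <- classify_recursive(g$matrix, seed = 307)
  expect_setequal(res$assignment$neuron_id, rownames(g$matrix))
  expect_false(anyNA(res$assignment$class))
  leaves <- axonclass:::collect_leaves(res$tree)
  expect_equal(sum(lengths(leaves)), nrow(g$matrix))
  expect_equal(anyDuplicated(unlist(leaves)), 0L)
  # the planted 3-neuron group is below the testable minimum: untested leaf
  expect_true("C3" %in% res$assignment$class)
})

test_that("single-class multinomial data stay a single class", {
  hits <- vapply(1:15, function(i) {
    g <- generate_matrix(k_classes = 1, n_per_class = 30, n_regions = 10,
                         seed = 400 + i)
    classify_recursive(g$matrix, seed = 500 + i)$n_classes == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a 52-neuron synthetic layer-6 matrix splits into classes of 21 and 31", {
  m <- read_matrix_csv(extdata("synthetic_m1l6_matrix.csv"))
  res <- classify_recursive(m, seed = 4202)
  expect_equal(res$n_classes, 2L)
  expect_setequal(as.integer(table(res$assignment$class)), c(21L, 31L))
  # the root gate must have fired, the two leaves must have stopped
  expect_identical(res$tree$levene$decision, "split")
  for (child in res$tree$children) {
    expect_identical(child$levene$decision, "stop")
  }
})

test_that("classification trees serialize to JSON", {
  g <- generate_matrix(k_classes = 2, n_per_class = 8, seed = 308)
  res <- classify_recursive(g$matrix, seed = 309)
  tf <- tempfile(fileext = ".json")
  write_classification_json(res, tf)
  parsed <- jsonlite::fromJSON(tf, simplifyVector = FALSE)
  expect_equal(parsed$n_classes, res$n_classes)
  expect_equal(length(parsed$tree$members), nrow(g$matrix))
})
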