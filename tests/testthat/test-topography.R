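test_that("hull volumes match closed forms", {
  expect_equal(hull_volume(unit_cube()), 1, tolerance = 1e-12)
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(hull_volume(tetra), 1 / 6, tolerance = 1e-12)
  # degenerate (coplanar) sets have zero volume
  flat <- cbind(matrix(runif(20), 10, 2), 0)
  expect_equal(hull_volume(flat), 0)
})

test_that("tiny or degenerate soma sets are returned unchanged", {
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  out <- remove_hull_outliers(tetra)
  expect_identical(out$points, tetra)
  expect_length(out$removed, 0L)

  three <- tetra[1:3, ]
  out3 <- remove_hull_outliers(three)
  expect_identical(out3$points, three)
})

test_that("a distant apex over a dense cloud is the sole flagged outlier", {
  pts <- rbind(cube_lattice(), c(0.5, 0.5, 3))
  out <- remove_hull_outliers(pts)
  # closed forms: V(full) = 1 + cone of height 2 over the top face = 5/3
  expect_equal(out$volume_full, 5 / 3, tolerance = 1e-9)
  expect_identical(out$removed, 28L)
  expect_equal(out$volume_trimmed, 1, tolerance = 1e-9)
  expect_equal(remove_hull_outliers(pts, sequential = TRUE)$removed, 28L)
})

test_that("when flagging would leave fewer than four points all are kept", {
  # every support corner of a far apex over a sparse cube carves > V/n
  pts <- rbind(unit_cube(), c(10, 10, 10))
  out <- remove_hull_outliers(pts)
  expect_length(out$removed, 0L)
  expect_match(out$note, "fewer than 4")
})

test_that("outlier removal never increases the hull volume", {
  set.seed(23)
  for (i in 1:5) {
    pts <- matrix(rnorm(3 * 25, sd = 100), ncol = 3)
    out <- remove_hull_outliers(pts)
    expect_lte(out$volume_trimmed, out$volume_full + 1e-9)
  }
})

test_that("hull overlap matches closed-form cube fixtures", {
  cube <- unit_cube()
  same <- hull_overlap(cube, cube)
  expect_equal(same$ratio, 1, tolerance = 1e-9)
  expect_false(same$empty_intersection)

  apart <- hull_overlap(cube, sweep(cube, 2L, c(10, 0, 0), "+"))
  expect_equal(apart$ratio, 0, tolerance = 1e-12)
  expect_true(apart$empty_intersection)

  shifted <- hull_overlap(cube, sweep(cube, 2L, c(0.5, 0, 0), "+"))
  expect_equal(shifted$v_intersection, 0.5, tolerance = 1e-9)
  expect_equal(shifted$v_union, 1.5, tolerance = 1e-9)
  expect_equal(shifted$ratio, 1 / 3, tolerance = 1e-9)
})

test_that("overlap is symmetric and obeys volume inequalities", {
  set.seed(24)
  for (i in 1:4) {
    a <- matrix(rnorm(3 * 15), ncol = 3)
    b <- matrix(rnorm(3 * 15, mean = 0.5), ncol = 3)
    ab <- hull_overlap(a, b)
    ba <- hull_overlap(b, a)
    expect_equal(ab$ratio, ba$ratio, tolerance = 1e-9)
    expect_gte(ab$ratio, 0)
    expect_lte(ab$ratio, 1)
    expect_lte(ab$v_intersection, min(ab$v_a, ab$v_b) + 1e-9)
    expect_lte(min(ab$v_a, ab$v_b), ab$v_union + 1e-9)
    expect_equal(ab$v_union, ab$v_a + ab$v_b - ab$v_intersection,
                 tolerance = 1e-9)
  }
})

test_that("exact intersection volumes agree with Monte-Carlo estimates", {
  set.seed(25)
  a <- matrix(rnorm(3 * 20), ncol = 3)
  b <- matrix(rnorm(3 * 20, mean = 0.8), ncol = 3)
  ov <- hull_overlap(a, b)
  ha <- convex_hull_3d(a)
  hb <- convex_hull_3d(b)
  lo <- pmin(apply(a, 2, min), apply(b, 2, min))
  hi <- pmax(apply(a, 2, max), apply(b, 2, max))
  n_mc <- 200000
  u <- cbind(runif(n_mc, lo[1], hi[1]), runif(n_mc, lo[2], hi[2]),
             runif(n_mc, lo[3], hi[3]))
  inside <- hull_contains(ha, u) & hull_contains(hb, u)
  box <- prod(hi - lo)
  p_hat <- mean(inside)
  se <- sqrt(p_hat * (1 - p_hat) / n_mc) * box
  expect_lte(abs(ov$v_intersection - p_hat * box), 3 * se + 1e-9)
})

test_that("degenerate hulls raise a geometry error", {
  flat <- cbind(matrix(runif(24), ncol = 2), 1)
  expect_error(hull_overlap(flat, unit_cube()), "degenerate")
})

test_that("layer composition counts and fractions", {
  all2 <- layer_composition(rep("L2", 7))
  expect_equal(all2$fraction, 1)

  mix <- layer_composition(c("L1", "L2", "L2", "L3"))
  expect_equal(mix$fraction[match(c("L1", "L2", "L3"), mix$layer)],
               c(0.25, 0.5, 0.25))

  # a class with 34 of 38 somata in layer 2 is 89.5% layer-2
  lc <- layer_composition(rep(c("L2", "L3"), c(34, 4)))
  expect_equal(round(100 * lc$fraction[lc$layer == "L2"], 1), 89.5)

  expect_error(layer_composition(c("L1", NA)), "unlabeled")
})

test_that("the class-wise hull report assembles overlaps and layers", {
  set.seed(26)
  somata <- rbind(
    data.frame(class = "A", x = rnorm(12, 0, 50), y = rnorm(12, 0, 50),
               z = rnorm(12, 0, 50), layer = "L2"),
    data.frame(class = "B", x = rnorm(12, 40, 50), y = rnorm(12, 0, 50),
               z = rnorm(12, 0, 50), layer = "L3"),
    data.frame(class = "C", x = 0, y = 0, z = 0, layer = "L1")
  )
  report <- soma_hull_report(somata)
  expect_s3_class(report, "hull_report")
  expect_setequal(names(report$classes), c("A", "B"))
  expect_identical(report$skipped, "C")
  expect_equal(nrow(report$overlaps), 1L)
  expect_true(all(report$overlaps$ratio >= 0 &
                    report$overlaps$ratio <= 1))
  expect_setequal(unique(report$layers$class), c("A", "B", "C"))
})
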