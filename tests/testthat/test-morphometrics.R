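test_that("main branch of a synthetic comb is recovered exactly", {
  comb <- make_comb_tree(seed = 3)
  at <- find_main_branch(comb$tree)
  expect_equal(at$tree$id[at$mb_tip], comb$mb_tip_id)
  expect_lt(abs(at$tree$x[at$mb_tip]), 1)
  expect_equal(at$tree$x[root_index(at$tree)], 0)
  expect_equal(at$tree$y[root_index(at$tree)], 0)
})

test_that("main-branch detection is equivariant under rigid motion", {
  comb <- make_comb_tree(seed = 5)
  at0 <- find_main_branch(comb$tree)
  moved <- translate_tree(rotate_tree(comb$tree, 37 * pi / 180), 12, -4)
  at1 <- find_main_branch(moved)
  expect_equal(at1$tree$id[at1$mb_tip], at0$tree$id[at0$mb_tip])
  expect_equal((at1$rotation_angle - at0$rotation_angle) * 180 / pi, -37,
               tolerance = 0.1)
  expect_equal(at1$tree$x, at0$tree$x, tolerance = 1e-8)
  expect_equal(at1$tree$y, at0$tree$y, tolerance = 1e-8)
})

test_that("a wide V-tree aligns along its longest path", {
  # opening angle 120 deg: after the longest arm is aligned vertically the
  # short arm points downwards, so both box corners resolve to the long tip
  a1 <- 4; a2 <- 3
  v <- dtree(x = c(0, 0, -a1 * sin(pi / 3), a2 * sin(pi / 3)),
             y = c(0, 1, 1 + a1 * cos(pi / 3), 1 + a2 * cos(pi / 3)),
             parent = c(0L, 1L, 2L, 2L))
  at <- find_main_branch(v)
  pv <- path_distances(at$tree)
  expect_equal(at$mb_tip, which.max(pv))
  expect_lt(abs(at$tree$x[at$mb_tip]), 1)
})

test_that("segment orientation angles fold into [0, 90] with the stated
           conventions", {
  t <- dtree(x = c(0, 0, 5, 0, 1), y = c(0, 5, 5, 10, 6),
             parent = c(0L, 1L, 2L, 2L, 2L))
  at <- find_main_branch(t)
  ang <- segment_orientation_angles(at)
  idx_h <- which(at$tree$id == 3)   # horizontal lateral segment
  idx_d <- which(at$tree$id == 5)   # diagonal (45 deg) segment
  expect_equal(ang[idx_h], 90, tolerance = 1e-6)
  expect_equal(ang[idx_d], 45, tolerance = 1e-6)
  expect_true(all(is.na(ang[at$mb_node_path])))
  # reflection across the MB leaves the folded angle unchanged
  t2 <- t; t2$x <- -t2$x
  at2 <- find_main_branch(t2)
  ang2 <- segment_orientation_angles(at2)
  expect_equal(ang2[which(at2$tree$id == 5)], 45, tolerance = 1e-6)
})

test_that("branch length order labels match an exhaustive oracle", {
  # path graph: everything is order 1
  p <- path_tree(6, n = 4)
  dec <- blo_decompose(p, root_index(p))
  expect_true(all(dec$blo[!is.na(dec$blo)] == 1L))
  # Y with arms 10 and 3: long arm continues order 1, short arm order 2
  y <- dtree(x = c(0, 0, 0, 3), y = c(0, 1, 11, 1),
             parent = c(0L, 1L, 2L, 2L))
  dec <- blo_decompose(y, 1L)
  expect_equal(dec$blo[3], 1L)
  expect_equal(dec$blo[4], 2L)
  # random multi-level subtrees against the oracle (coarse node spacing
  # keeps the oracle's per-node recursion shallow)
  for (seed in 1:5) {
    comb <- make_comb_tree(comb_params(ho_rate = 2.5, spacing = 2),
                           seed = seed)
    t <- comb$tree
    dec <- blo_decompose(t, root_index(t))
    expect_equal(dec$blo, blo_oracle(t, root_index(t)))
  }
})

test_that("branch table recovers the planted comb ground truth", {
  for (seed in c(3, 9)) {
    comb <- make_comb_tree(seed = seed)
    at <- find_main_branch(comb$tree)
    br <- branch_table(at)
    br$tip_id <- at$tree$id[br$tip]
    m <- merge(comb$branches, br, by = "tip_id")
    expect_equal(nrow(m), nrow(comb$branches))
    expect_equal(m$blo.x, m$blo.y)
    expect_equal(m$order_class.x, m$order_class.y)
    expect_equal(m$length.x, m$length.y, tolerance = 1e-9)
    expect_equal(m$mean_angle.x, m$mean_angle.y, tolerance = 0.1)
  }
})

test_that("morphometrics handle degenerate trees and match brute force", {
  p <- path_tree(10, n = 6)
  mv <- compute_morphometrics(p)
  expect_equal(unname(mv["n_branch_points"]), 0)
  expect_equal(unname(mv["total_length"]), 10)
  expect_equal(unname(mv["max_branch_order"]), 0)
  expect_true(is.na(mv["mean_van_pelt_asymmetry"]))
  # perfectly symmetric binary tree: Van Pelt asymmetry 0 everywhere
  sym <- dtree(x = c(0, 0, -2, 2, -3, -1, 1, 3),
               y = c(0, 1, 2, 2, 3, 3, 3, 3),
               parent = c(0L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  mv2 <- compute_morphometrics(sym)
  expect_equal(unname(mv2["mean_van_pelt_asymmetry"]), 0)
  expect_equal(unname(mv2["n_terminals"]), 4)
})

test_that("selected morphometrics equal independent recomputations", {
  comb <- make_comb_tree(seed = 7)
  t <- comb$tree
  mv <- compute_morphometrics(t)
  expect_equal(unname(mv["n_branch_points"]), sum(is_branch_point(t)))
  expect_equal(unname(mv["n_terminals"]), sum(is_terminal(t)))
  expect_equal(unname(mv["total_length"]), total_length(t))
  seg <- segment_lengths(t)
  expect_equal(unname(mv["total_surface"]), sum(pi * 2 * t$r * seg))
  expect_equal(unname(mv["total_volume"]), sum(pi * t$r^2 * seg))
  rt <- root_index(t)
  eucl <- sqrt((t$x - t$x[rt])^2 + (t$y - t$y[rt])^2 + (t$z - t$z[rt])^2)
  expect_equal(unname(mv["max_euclidean_distance"]), max(eucl))
  expect_equal(unname(mv["mean_euclidean_distance"]), mean(eucl))
  expect_equal(unname(mv["max_path_distance"]), max(path_distances(t)))
  bo <- branch_order(t)
  expect_equal(unname(mv["mean_euclidean_compactness"]),
               mean(eucl / (bo + 1)))
  expect_true(all(is.finite(mv[c("spanning_area", "cable_density",
                                 "field_width", "field_height",
                                 "scaled_length")])))
})

test_that("scaled length corresponds to a spanning area of exactly 100", {
  comb <- make_comb_tree(seed = 4)
  scaled <- scale_to_area(comb$tree, 100)
  expect_equal(spanning_area(scaled), 100, tolerance = 0.1)
  mv <- compute_morphometrics(comb$tree)
  expect_equal(unname(mv["scaled_length"]), total_length(scaled),
               tolerance = 1e-6)
})

test_that("bootstrap median test behaves at the extremes and is seeded", {
  same <- bootstrap_median_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5),
                                n_boot = 2000, seed = 1)
  expect_equal(same$difference, 0)
  expect_gt(same$p_value, 0.5)
  const <- bootstrap_median_test(rep(2, 10), rep(2, 12), n_boot = 1000)
  expect_equal(const$p_value, 1)
  set.seed(10)
  shifted <- replicate(20, {
    bootstrap_median_test(rnorm(200), rnorm(200, 2), n_boot = 1000)$p_value
  })
  expect_true(all(shifted < 0.001))
  set.seed(99)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  r1 <- bootstrap_median_test(a, b, n_boot = 1000, seed = 7)
  set.seed(123)  # seed argument must shield against outer RNG state
  r2 <- bootstrap_median_test(a, b, n_boot = 1000, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
})
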