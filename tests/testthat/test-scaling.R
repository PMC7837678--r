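test_that("the scaling law evaluates as sqrt(S N / pi)", {
  expect_equal(scaling_law_length(100, 100), 100 / sqrt(pi))
  expect_equal(scaling_law_length(100, 100), 56.42, tolerance = 1e-3)
  expect_equal(scaling_law_length(250, 0), 0)
  # quadrupling N doubles L at fixed S
  expect_equal(scaling_law_length(100, 48), 2 * scaling_law_length(100, 12))
})

test_that("greedy MST construction handles base cases", {
  t1 <- generate_mst_tree(matrix(c(3, 4), 1), root = c(0, 0))
  expect_equal(n_nodes(t1), 2)
  expect_equal(total_length(t1), 5)
  # bf = 0 on collinear targets gives a chain (pure wire minimisation)
  tc <- generate_mst_tree(cbind(c(1, 2, 3), 0), root = c(0, 0), bf = 0)
  expect_equal(sum(is_branch_point(tc)), 0)
  expect_equal(total_length(tc), 3)
  # duplicate target coincident with cable is skipped with a message
  expect_message(
    generate_mst_tree(rbind(c(1, 0), c(1, 0)), root = c(0, 0)),
    "coincident")
})

test_that("total wire length is monotone in the balancing factor", {
  set.seed(2)
  cloud <- cbind(runif(20, 0, 10), runif(20, 0, 10))
  l0 <- total_length(generate_mst_tree(cloud, c(5, 5), bf = 0))
  l1 <- total_length(generate_mst_tree(cloud, c(5, 5), bf = 1))
  expect_gte(l1, l0)
})

test_that("interstitial attachment creates one branch point per split", {
  set.seed(3)
  t <- generate_mst_tree(cbind(runif(60, 0, 10), runif(60, 0, 10)),
                         root = c(5, 5), record = TRUE)
  rec <- attr(t, "record")
  expect_true(all(diff(rec$L) > 0))          # cable grows monotonically
  expect_true(all(diff(rec$N) >= 0))
  expect_equal(rec$N[nrow(rec)], sum(is_branch_point(t)))
  expect_equal(rec$L[nrow(rec)], total_length(t), tolerance = 1e-9)
})

test_that("area normalisation scales lengths by the square-root factor", {
  comb <- make_comb_tree(seed = 6)$tree
  s0 <- spanning_area(comb, method = "convex")
  scaled <- scale_to_area(comb, 100, method = "convex")
  f <- sqrt(100 / s0)
  expect_equal(total_length(scaled), total_length(comb) * f,
               tolerance = 1e-9)
  expect_equal(spanning_area(scaled, method = "convex"), 100,
               tolerance = 1e-6)
  # already at the target: identity
  again <- scale_to_area(scaled, 100, method = "convex")
  expect_equal(again$x, scaled$x, tolerance = 1e-9)
})

test_that("OLS of L on sqrt(N) reproduces an exact scaling line", {
  N <- c(10, 50, 100, 200, 400)
  fit <- suppressWarnings(   # lm warns about the numerically perfect fit
    fit_scaling(data.frame(N = N, L = sqrt(100 * N / pi))))
  expect_equal(fit$slope, 10 / sqrt(pi), tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_scaling(data.frame(N = c(4, 4, 4), L = 1:3)),
               "constant")
})

test_that("tight boundary recovers known areas", {
  sq <- as.matrix(expand.grid(seq(0, 10, 0.5), seq(0, 10, 0.5)))
  expect_equal(convex_area(sq), 100)
  expect_equal(tight_boundary(sq)$area, 100, tolerance = 0.5)
  # an L-shaped cloud: the concave boundary is much tighter than the hull
  Lsh <- unique(rbind(
    as.matrix(expand.grid(seq(0, 10, 0.5), seq(0, 2, 0.5))),
    as.matrix(expand.grid(seq(0, 2, 0.5), seq(0, 10, 0.5)))))
  expect_equal(convex_area(Lsh), 68)
  expect_equal(tight_boundary(Lsh)$area, 36, tolerance = 0.5)
  expect_equal(convex_area(rbind(c(0, 0), c(1, 0))), 0)
})
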