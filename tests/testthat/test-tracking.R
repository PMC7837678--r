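test_that("identical frames match perfectly and classify stable", {
  comb <- make_comb_tree(seed = 4)$tree
  tips <- which(is_terminal(comb))
  reg <- data.frame(node_id = tips, track_id = seq_along(tips))
  pairs <- match_branches(comb, comb, reg, reg)
  expect_equal(nrow(pairs), length(tips))
  ev <- classify_dynamics(pairs, 17.5, 18.5)
  expect_true(all(ev$class == "stable"))
  expect_true(all(ev$delta_length == 0))
})

test_that("classification thresholds and rates follow the definitions", {
  pairs <- data.frame(track_id = 1:5,
                      tip0 = c(1, 2, 3, 4, NA),
                      tip1 = c(11, 12, 13, NA, 15),
                      length0 = c(5, 5, 5, 2.5, NA),
                      length1 = c(5.2, 8, 3.1, NA, 1.9))
  ev <- classify_dynamics(pairs, 18, 19, resolution = 0.3)
  expect_equal(ev$class, c("stable", "elongated", "shortened",
                           "retracted", "new"))
  expect_equal(ev$rate[2], 3)
  expect_equal(ev$rate[4], -2.5)
  expect_error(classify_dynamics(pairs, 19, 18), "later")
})

test_that("ambiguous registration is rejected", {
  comb <- make_comb_tree(seed = 4)$tree
  tips <- which(is_terminal(comb))
  reg <- data.frame(node_id = tips, track_id = seq_along(tips))
  bad <- reg; bad$track_id[2] <- bad$track_id[1]
  expect_error(match_branches(comb, comb, bad, reg), "one-to-many")
})

test_that("planted time-lapse events are recovered exactly", {
  comb <- make_comb_tree(seed = 5)
  tl <- make_timelapse(base = comb$tree, seed = 7)
  ev <- track_series(tl)
  m <- merge(tl$events, ev, by = c("track_id", "t0", "t1"),
             suffixes = c(".gt", ".an"))
  expect_equal(nrow(m), nrow(tl$events))
  expect_equal(nrow(m), nrow(ev))
  expect_true(all(m$class.gt == m$class.an))
  expect_equal(m$delta_length.gt, m$delta_length.an, tolerance = 1e-9)
})

test_that("dynamics summary fractions sum to one and recover planted
           fractions within binomial error", {
  comb <- make_comb_tree(seed = 5)
  tp <- timelapse_params()
  tl <- make_timelapse(tp, base = comb$tree, seed = 7)
  summ <- dynamics_summary(track_series(tl))
  fr <- summ$frac_new + summ$frac_retracted + summ$frac_shortened +
        summ$frac_elongated + summ$frac_stable
  expect_equal(fr, rep(1, nrow(summ)))
  # realised ground-truth fractions per bin match the analysis exactly
  gt <- tl$events
  for (i in seq_len(nrow(summ))) {
    g <- gt[gt$t1 == summ$bin_end[i], ]
    expect_equal(summ$frac_new[i], mean(g$class == "new"))
    expect_equal(summ$n[i], nrow(g))
  }
  # planted per-transition fractions are defined relative to the branches
  # present at the earlier frame; newly formed branches enter the summary
  # denominator, so rescale by (1 - frac_new) before comparing
  n0 <- summ$n * (1 - summ$frac_new)
  red <- (summ$frac_retracted + summ$frac_shortened) / (1 - summ$frac_new)
  ci <- 1.96 * sqrt(tp$frac_reduced * (1 - tp$frac_reduced) / n0)
  expect_true(all(abs(red - tp$frac_reduced) <= ci))
  elo <- summ$frac_elongated / (1 - summ$frac_new)
  ci_e <- 1.96 * sqrt(tp$frac_elongated * (1 - tp$frac_elongated) / n0)
  expect_true(all(abs(elo - tp$frac_elongated) <= ci_e))
})

test_that("planted rates in the 2-3 um/hr regime are recovered", {
  comb <- make_comb_tree(seed = 6)
  tp <- timelapse_params()
  tl <- make_timelapse(tp, base = comb$tree, seed = 9)
  summ <- dynamics_summary(track_series(tl))
  red <- stats::weighted.mean(summ$mean_reduction_rate, summ$n)
  ext <- stats::weighted.mean(summ$mean_extension_rate, summ$n)
  expect_gt(red, 1.5); expect_lt(red, 3.5)
  expect_gt(ext, 1.5); expect_lt(ext, 3.5)
})

test_that("all-stable parameters produce identical frames", {
  comb <- make_comb_tree(seed = 3)
  tp <- timelapse_params(frac_reduced = rep(0, 5), frac_new = rep(0, 5),
                         frac_elongated = rep(0, 5))
  tl <- make_timelapse(tp, base = comb$tree, seed = 2)
  for (f in 2:length(tl$trees))
    expect_identical(tl$trees[[f]]$x, tl$trees[[1]]$x)
  expect_true(all(tl$events$class == "stable"))
})
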