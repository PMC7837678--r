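test_that("growth additions respect the radius cap and the arena", {
  comb <- make_comb_tree(seed = 3)
  arena <- make_arena(comb$tree)
  p <- growth_params(n_probe = 2000, b_r = 6)
  set.seed(1)
  t1 <- grow_step(resample_tree(arena$mb, p$attach_spacing), arena, p,
                  radius = 2.5, n_add = 10)
  expect_true(all(points_in_polygon(cbind(t1$x, t1$y), arena$contour)))
  expect_true(all(segment_lengths(t1) <= 2.5 + 1e-9))
  expect_gt(n_nodes(t1), n_nodes(arena$mb))
})

test_that("retraction step handles the degenerate fractions", {
  comb <- make_comb_tree(seed = 3)
  arena <- make_arena(comb$tree)
  p <- growth_params(n_probe = 2000)
  tree <- resample_tree(comb$tree, p$attach_spacing)
  set.seed(2)
  bin0 <- data.frame(bin_end = 20.5, shorten_fraction = 0,
                     new_fraction = 0, shorten_length = 2)
  expect_identical(retraction_step(tree, arena, p, bin0), tree)
  bin1 <- data.frame(bin_end = 20.5, shorten_fraction = 1,
                     new_fraction = 0, shorten_length = 1e4)
  simple <- bare_comb(lateral_lengths = c(2, 3, 4), mb_height = 6)
  arena2 <- growth_arena(simple, cbind(c(-6, 6, 6, -6), c(-1, -1, 8, 8)))
  bare <- retraction_step(simple, arena2, p, bin1)
  # every terminal branch (laterals and MB tip) removed in one pass
  expect_equal(sum(is_terminal(bare)), 1)
  expect_equal(sum(is_branch_point(bare)), 0)
  expect_lt(total_length(bare), total_length(simple))
})

test_that("expected removed cable matches the Monte-Carlo mean", {
  comb <- bare_comb(lateral_lengths = c(1, 2, 3, 4), mb_height = 6)
  arena <- growth_arena(comb, cbind(c(-6, 6, 6, -6), c(-1, -1, 8, 8)))
  p <- growth_params(n_probe = 500)
  bin <- data.frame(bin_end = 20.5, shorten_fraction = 0.5,
                    new_fraction = 0, shorten_length = 1.5)
  set.seed(3)
  removed <- replicate(300, {
    total_length(comb) - total_length(retraction_step(comb, arena, p, bin))
  })
  # 3 of the 5 terminal branches (4 laterals + MB tip of length 2) chosen
  # uniformly; each loses min(1.5, length) of cable
  per_branch <- pmin(1.5, c(1, 2, 3, 4, 2))
  expected <- 3 * mean(per_branch)
  expect_equal(mean(removed), expected, tolerance = 0.1)
})

test_that("pure growth is monotone and seeded runs reproduce bit-exact", {
  comb <- make_comb_tree(seed = 3)
  arena <- make_arena(comb$tree)
  p0 <- growth_params(n_probe = 2000, b_r = 6,
                      retraction_times = numeric(0))
  sim <- simulate_development(arena, p0, seed = 11)
  N <- vapply(sim$trees, function(t) sum(is_branch_point(t)), integer(1))
  expect_true(all(diff(N) >= 0))
  final <- sim$trees[[length(sim$trees)]]
  expect_true(all(points_in_polygon(cbind(final$x, final$y),
                                    arena$contour)))
  sim2 <- simulate_development(arena, p0, seed = 11)
  expect_identical(sim2$trees[[length(sim2$trees)]], final)
  sim3 <- simulate_development(arena, p0, seed = 12)
  expect_false(identical(n_nodes(sim3$trees[[length(sim3$trees)]]),
                         n_nodes(final)) &&
               identical(sim3$trees[[length(sim3$trees)]]$x, final$x))
})

test_that("doubling the branch rate doubles expected additions", {
  comb <- make_comb_tree(seed = 3)
  arena <- make_arena(comb$tree)
  n_new <- function(br, seed) {
    p <- growth_params(n_probe = 1000, b_r = br,
                       retraction_times = numeric(0), t_stop = 17.5)
    sim <- simulate_development(arena, p, seed = seed)
    n_nodes(sim$trees[[length(sim$trees)]]) - n_nodes(sim$trees[[1]])
  }
  lo <- vapply(1:12, function(s) n_new(3, s), numeric(1))
  hi <- vapply(1:12, function(s) n_new(6, s), numeric(1))
  expect_equal(mean(hi) / mean(lo), 2, tolerance = 0.35)
})

test_that("growth parameters are recovered from a planted series", {
  young <- make_comb_tree(comb_params(n_laterals = 12, ho_rate = 1.2),
                          seed = 1)
  tp <- timelapse_params()
  tl <- make_timelapse(tp, base = young$tree, seed = 2)
  ev <- track_series(tl)
  gp <- extract_growth_parameters(tl, ev, t_start = 16)
  # addition rate: new + elongating events per 15-min interval
  n_add <- sum(ev$class %in% c("new", "elongated") & ev$t1 <= 19.5)
  expect_equal(gp$b_r, n_add / ((19.5 - 16.5) * 4))
  # growth radius: mean length of newly formed branches, close to the
  # planted pre-switch value (2.5 um)
  new_pre <- ev$delta_length[ev$class == "new" & ev$t1 <= 19.5]
  expect_equal(gp$r_grow_pre, mean(new_pre))
  ci <- 1.96 * tp$new_len_sd / sqrt(length(new_pre))
  expect_lt(abs(gp$r_grow_pre - tp$new_len_mean_pre), ci + 0.05)
  # per-bin shorten lengths equal the mean retracted branch lengths
  summ <- dynamics_summary(ev)
  expect_equal(gp$bins$shorten_fraction,
               summ$frac_retracted + summ$frac_shortened)
  # missing bins are reported
  expect_error(extract_growth_parameters(tl, ev[ev$t1 < 20, ],
                                         t_start = 16),
               "bin")
})
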