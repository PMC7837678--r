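test_that("removal count comes from the peak-to-trough branch-point
           difference", {
  expect_equal(plan_removal_count(c(10, 25, 12)), 13)
  expect_warning(expect_equal(plan_removal_count(c(5, 5, 5)), 0),
                 "no retraction")
  # planted removals on a comb are recovered from the tree series
  comb <- make_comb_tree(comb_params(ho_rate = 2), seed = 8)$tree
  series <- list(comb)
  cur <- comb
  set.seed(1)
  for (i in 1:7) {
    tb <- dissect_terminal_branches(cur)
    at <- find_main_branch(cur)
    tb <- tb[tb$tip != at$mb_tip, ]
    # only remove branches that take a branch point with them
    ok <- tb$start[vapply(tb$start, function(s)
      sum(cur$parent == s), integer(1)) == 2]
    row <- which(tb$start %in% ok)[1]
    cur <- remove_terminal_branch(cur, tb$tip[row])
    series[[i + 1]] <- cur
  }
  expect_equal(plan_removal_count(series), 7)
})

test_that("sorted schemes remove branches in the documented order", {
  comb <- bare_comb(lateral_lengths = c(1, 2, 3, 4, 5), mb_height = 7,
                    top_pair = 6)
  out <- apply_retraction_scheme(comb, "shortest_first", n_remove = 2)
  # the two shortest laterals (heights 1 and 2) are gone, the rest intact
  lat_heights <- function(t)
    sort(unique(t$y[abs(t$x) > 0.5 & t$y %in% 1:5]))
  expect_equal(lat_heights(out), c(3, 4, 5))
  expect_equal(sum(is_terminal(out)), sum(is_terminal(comb)) - 2)
  # low angle first: the one near-vertical lateral goes first
  t <- bare_comb(lateral_lengths = c(3, 3, 3), mb_height = 5, top_pair = 4)
  tipv <- which(abs(t$x) > 0.5 & t$y <= 3)[1]   # a lateral tip
  t$x[tipv] <- 0.2; t$y[tipv] <- t$y[t$parent[tipv]] + 3
  out2 <- apply_retraction_scheme(t, "low_angle_first", n_remove = 1)
  expect_false(any(abs(out2$x - 0.2) < 1e-9))
  expect_equal(sum(is_terminal(out2)), sum(is_terminal(t)) - 1)
  # higher branch length order first
  comb2 <- make_comb_tree(comb_params(ho_rate = 2), seed = 2)
  n_higher <- sum(comb2$branches$order_class == "higher_order")
  out3 <- apply_retraction_scheme(comb2$tree, "high_blo_first",
                                  n_remove = min(3, n_higher))
  br3 <- branch_table(find_main_branch(out3))
  expect_equal(sum(br3$order_class == "higher_order"), n_higher - 3)
})

test_that("each removal changes topology by exactly one terminal", {
  comb <- make_comb_tree(seed = 12)$tree
  cur <- comb
  set.seed(5)
  for (i in 1:6) {
    tb <- dissect_terminal_branches(cur)
    at <- find_main_branch(cur)
    tb <- tb[tb$tip != at$mb_tip, ]
    nxt <- remove_terminal_branch(cur, tb$tip[sample.int(nrow(tb), 1)])
    expect_equal(sum(is_terminal(nxt)), sum(is_terminal(cur)) - 1)
    expect_true((sum(is_branch_point(cur)) - sum(is_branch_point(nxt)))
                %in% c(0L, 1L))
    expect_lt(total_length(nxt), total_length(cur))
    cur <- nxt
  }
})

test_that("the random scheme is reproducible and exhaustive removal
           strips the tree to its main branch", {
  comb <- bare_comb(lateral_lengths = c(2, 3, 4, 5), mb_height = 6)
  n_avail <- nrow(dissect_terminal_branches(comb)) - 1L
  reps <- apply_retraction_scheme(comb, "random", n_remove = n_avail,
                                  n_reps = 3, seed = 42)
  for (r in reps) {
    expect_equal(sum(is_branch_point(r)), 0)
    expect_equal(sum(is_terminal(r)), 1)
  }
  r1 <- apply_retraction_scheme(comb, "random", 2, n_reps = 2, seed = 9)
  r2 <- apply_retraction_scheme(comb, "random", 2, n_reps = 2, seed = 9)
  expect_identical(r1, r2)
  expect_error(apply_retraction_scheme(comb, "random", n_avail + 2),
               "exceeds|removable")
})

test_that("scheme comparison reports zero distance for identical trees", {
  comb <- make_comb_tree(seed = 3)$tree
  pruned <- apply_retraction_scheme(comb, "shortest_first", 3)
  cmp <- compare_schemes(list(self = pruned), pruned, n_boot = 1000)
  expect_equal(cmp$angle_emd, 0)
  expect_equal(cmp$bp_count_error, 0)
  expect_equal(cmp$total_length_error, 0)
})
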