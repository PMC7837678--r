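#' Number of branches to remove for a retraction simulation
#'
#' Given the branch-point counts of a developmental time series, returns
#' the difference between the maximum (the tree just before retraction)
#' and the subsequent minimum (the tree after retraction). A series whose
#' counts never decrease after the maximum yields 0 with a warning.
#'
#' @param n_branch_points numeric vector of branch-point counts, ordered in
#'   time (or a list of [dtree]s, in which case the counts are computed).
#' @return integer removal count.
#' @export
plan_removal_count <- function(n_branch_points) {
  if (is.list(n_branch_points) && inherits(n_branch_points[[1]], "dtree"))
    n_branch_points <- vapply(n_branch_points,
                              function(t) sum(is_branch_point(t)), integer(1))
  stopifnot(length(n_branch_points) >= 1)
  i_max <- which.max(n_branch_points)
  post <- n_branch_points[i_max:length(n_branch_points)]
  n <- n_branch_points[i_max] - min(post)
  if (n == 0L) warning("no retraction detected in series; removal count 0")
  as.integer(n)
}

# per-terminal-branch sort keys on the current tree; MB tip excluded
.terminal_branch_keys <- function(t, need_angles, need_blo) {
  tb <- dissect_terminal_branches(t)
  at <- find_main_branch(t)
  tb <- tb[tb$tip != at$mb_tip, , drop = FALSE]
  if (need_angles) {
    ang <- segment_orientation_angles(at)
    tb$mean_angle <- vapply(tb$node_path, function(p) {
      a <- ang[p[-1]]
      if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
    }, numeric(1))
  }
  if (need_blo) {
    br <- branch_table(at)
    tb$blo <- br$blo[match(tb$tip, br$tip)]
  }
  tb
}

#' Apply an in-silico terminal-branch retraction scheme
#'
#' Removes `n_remove` terminal branches from a pre-retraction tree under
#' one of four schemes: `"shortest_first"` (ascending cable length),
#' `"low_angle_first"` (ascending mean segment orientation angle),
#' `"high_blo_first"` (descending branch length order), or `"random"`
#' (uniform selection; returns an ensemble of `n_reps` trees). The main
#' branch tip is never eligible: retraction targets lateral branches.
#'
#' By default the terminal-branch set is re-dissected (and sorted keys
#' recomputed) after every removal, so cable exposed by a removal becomes
#' part of a longer terminal branch and is eligible with its updated key;
#' `static_list = TRUE` instead sorts the initial terminal-branch list once
#' and removes the first `n_remove` entries. Sort ties are broken by the
#' stable original branch (tip index) order.
#'
#' @param t a [dtree] (pre-retraction morphology).
#' @param scheme one of `"shortest_first"`, `"low_angle_first"`,
#'   `"high_blo_first"`, `"random"`.
#' @param n_remove number of terminal branches to remove.
#' @param n_reps ensemble size for the random scheme.
#' @param seed optional integer seed (random scheme).
#' @param static_list remove from the initial branch list without
#'   re-dissection.
#' @return a [dtree], or a list of `n_reps` [dtree]s for `"random"`.
#' @export
apply_retraction_scheme <- function(t, scheme = c("shortest_first",
                                                  "low_angle_first",
                                                  "high_blo_first",
                                                  "random"),
                                    n_remove, n_reps = 100, seed = NULL,
                                    static_list = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(n_remove >= 0)
  n_avail <- nrow(.terminal_branch_keys(t, FALSE, FALSE))
  if (n_remove > n_avail)
    stop("n_remove (", n_remove, ") exceeds the ", n_avail,
         " removable terminal branches")
  if (scheme == "random") {
    if (!is.null(seed)) set.seed(seed)
    return(lapply(seq_len(n_reps), function(rep) {
      cur <- t
      for (i in seq_len(n_remove)) {
        tb <- .terminal_branch_keys(cur, FALSE, FALSE)
        if (nrow(tb) == 0L) stop("no removable terminal branches left")
        pick <- tb$tip[sample.int(nrow(tb), 1L)]
        cur <- remove_terminal_branch(cur, pick)
      }
      cur
    }))
  }
  need_angles <- scheme == "low_angle_first"
  need_blo <- scheme == "high_blo_first"
  key_order <- function(tb) {
    key <- switch(scheme,
                  shortest_first = tb$length,
                  low_angle_first = tb$mean_angle,
                  high_blo_first = -as.numeric(tb$blo))
    order(key, na.last = TRUE)
  }
  if (static_list) {
    tb <- .terminal_branch_keys(t, need_angles, need_blo)
    sel <- tb[key_order(tb), ][seq_len(n_remove), ]
    drop <- unlist(lapply(sel$node_path, function(p) p[-1]))
    return(drop_nodes(t, unique(drop)))
  }
  cur <- t
  for (i in seq_len(n_remove)) {
    tb <- .terminal_branch_keys(cur, need_angles, need_blo)
    if (nrow(tb) == 0L) stop("no removable terminal branches left")
    pick <- tb$tip[key_order(tb)[1]]
    cur <- remove_terminal_branch(cur, pick)
  }
  cur
}

# first Wasserstein distance between two empirical 1D distributions
emd1d <- function(x, y, n_q = 201) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  p <- seq(0, 1, length.out = n_q)
  mean(abs(stats::quantile(x, p, names = FALSE, type = 7) -
           stats::quantile(y, p, names = FALSE, type = 7)))
}

# distribution + count summary of one tree used for scheme comparison
.scheme_summary <- function(t) {
  at <- find_main_branch(t)
  br <- branch_curvature_increase(branch_table(at))
  list(angles = br$mean_angle,
       curvature = br$curvature,
       lengths = br$length,
       n_branch_points = sum(is_branch_point(t)),
       n_second = sum(br$order_class == "second_order"),
       n_higher = sum(br$order_class == "higher_order"),
       total_length = total_length(t))
}

#' Compare retraction-scheme outputs against a reference morphology
#'
#' Summarises each simulated post-retraction tree (or ensemble) and
#' measures its distance to the reference post-retraction tree:
#' 1-Wasserstein distances between the per-branch mean-angle, curvature
#' and branch-length distributions, plus absolute errors on branch-point,
#' second-order and higher-order branch counts and total cable length.
#' Ensembles (the random scheme) are averaged over replicates. Bootstrap
#' median tests compare each scheme's pooled per-branch angles with the
#' reference.
#'
#' @param sim_trees named list; each element a [dtree] or a list of
#'   [dtree]s (one entry per scheme).
#' @param real_post_tree the reference [dtree] after retraction.
#' @param n_boot bootstrap resamples for the median tests.
#' @param seed seed for the bootstrap tests.
#' @return data.frame with one row per scheme, including `angle_emd` and
#'   `rank_angle` (1 = closest angle distribution).
#' @export
compare_schemes <- function(sim_trees, real_post_tree, n_boot = 1000,
                            seed = 1) {
  ref <- .scheme_summary(real_post_tree)
  rows <- lapply(names(sim_trees), function(nm) {
    trees <- sim_trees[[nm]]
    if (inherits(trees, "dtree")) trees <- list(trees)
    sums <- lapply(trees, .scheme_summary)
    ang <- mean(vapply(sums, function(s) emd1d(s$angles, ref$angles),
                       numeric(1)), na.rm = TRUE)
    crv <- mean(vapply(sums, function(s) emd1d(s$curvature, ref$curvature),
                       numeric(1)), na.rm = TRUE)
    lng <- mean(vapply(sums, function(s) emd1d(s$lengths, ref$lengths),
                       numeric(1)), na.rm = TRUE)
    pooled_ang <- unlist(lapply(sums, `[[`, "angles"))
    bt <- bootstrap_median_test(pooled_ang[!is.na(pooled_ang)],
                                ref$angles[!is.na(ref$angles)],
                                n_boot = max(n_boot, 1000), seed = seed)
    data.frame(
      scheme = nm,
      angle_emd = ang,
      curvature_emd = crv,
      length_emd = lng,
      bp_count_error = mean(vapply(
        sums, function(s) abs(s$n_branch_points - ref$n_branch_points),
        numeric(1))),
      higher_order_error = mean(vapply(
        sums, function(s) abs(s$n_higher - ref$n_higher), numeric(1))),
      second_order_error = mean(vapply(
        sums, function(s) abs(s$n_second - ref$n_second), numeric(1))),
      total_length_error = mean(vapply(
        sums, function(s) abs(s$total_length - ref$total_length),
        numeric(1))),
      angle_median_diff = bt$difference,
      angle_median_p = bt$p_value)
  })
  out <- do.call(rbind, rows)
  out$rank_angle <- rank(out$angle_emd, ties.method = "min")
  out
}
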