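# Small tree builders and independent oracles shared across the suite.

path_tree <- function(length = 10, n = 3) {
  dtree(x = rep(0, n), y = seq(0, length, length.out = n),
        parent = c(0L, seq_len(n - 1L)))
}

y_tree <- function(arm1 = 2, arm2 = 2, stem = 1) {
  # root -> stem top -> two arms spreading diagonally
  dtree(x = c(0, 0, -arm1 / sqrt(2), arm2 / sqrt(2)),
        y = c(0, stem, stem + arm1 / sqrt(2), stem + arm2 / sqrt(2)),
        parent = c(0L, 1L, 2L, 2L))
}

# comb with a vertical MB and horizontal laterals of given lengths,
# attached at heights 1, 2, ... (one node per segment endpoint).
# top_pair adds two steep branches at the MB tip so that the tip is a
# branch point and the main branch is unambiguously recoverable.
bare_comb <- function(lateral_lengths, mb_height = length(lateral_lengths) + 1,
                      top_pair = 0) {
  x <- 0; y <- 0; parent <- 0L
  for (h in seq_len(mb_height)) {
    x <- c(x, 0); y <- c(y, h); parent <- c(parent, h)
  }
  side <- 1
  for (i in seq_along(lateral_lengths)) {
    x <- c(x, side * lateral_lengths[i]); y <- c(y, i)
    parent <- c(parent, i + 1L)   # MB node at height i
    side <- -side
  }
  if (top_pair > 0) {
    tip <- mb_height + 1L
    for (s in c(-1, 1)) {
      x <- c(x, s * top_pair * sin(70 * pi / 180))
      y <- c(y, mb_height - top_pair * cos(70 * pi / 180))
      parent <- c(parent, tip)
    }
  }
  dtree(x = x, y = y, parent = parent)
}

# independent branch-length-order oracle: repeatedly peel the metric-longest
# root-to-tip path (recursive, string-free reimplementation)
blo_oracle <- function(t, entry) {
  seg <- segment_lengths(t)
  kids <- children_list(t)
  labels <- rep(NA_integer_, n_nodes(t))
  all_paths <- function(v) {
    ch <- kids[[v]]
    if (is.null(ch) || length(ch) == 0L) return(list(v))
    unlist(lapply(ch, function(c0)
      lapply(all_paths(c0), function(p) c(v, p))), recursive = FALSE)
  }
  assign_blo <- function(start, k) {
    paths <- all_paths(start)
    lens <- vapply(paths, function(p) sum(seg[p[-1]]) + seg[p[1]], numeric(1))
    best <- max(lens)
    cand <- which(lens >= best - 1e-12)
    tips <- vapply(paths[cand], function(p) p[length(p)], integer(1))
    main <- paths[[cand[which.min(tips)]]]
    labels[main] <<- k
    for (v in main) {
      for (c0 in setdiff(kids[[v]], main)) assign_blo(c0, k + 1L)
    }
  }
  assign_blo(entry, 1L)
  labels
}

# numeric geometry oracle for the bending model: construct the plane/
# cylinder intersection curve, measure its semi-diameters numerically and
# apply the circular-arc approximation
curvature_oracle <- function(theta, a = 1.7) {
  dist2 <- function(u) {
    p <- c(a * cos(u), a * sin(u), a * sin(u) / tan(theta))
    sum(p^2)
  }
  dmax <- sqrt(stats::optimize(dist2, c(0, pi), maximum = TRUE,
                               tol = 1e-14)$objective)
  dmin <- sqrt(stats::optimize(dist2, c(-pi / 4, pi / 2),
                               tol = 1e-14)$objective)
  rc <- (dmax + dmin) / 2
  (1 / rc) / (1 / a)   # c1 rescaled by its value at theta = pi/2
}
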