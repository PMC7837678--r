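#' Topological sections of a tree
#'
#' Splits the tree into unbranched sections: each section runs from a
#' topological point (root or branch point) to the next branch point or
#' terminal, inclusive of both ends.
#'
#' @param t a [dtree].
#' @return list of integer node-index vectors, ordered root-outward.
#' @export
tree_sections <- function(t) {
  topo <- is_branch_point(t) | is_terminal(t)
  ends <- which((is_branch_point(t) | is_terminal(t)) & t$parent != 0L)
  # also sections ending at a branch point that is the root's only child chain
  out <- lapply(ends, function(e) {
    path <- e
    p <- t$parent[e]
    while (p != 0L && !topo[p]) {
      path <- c(p, path)
      p <- t$parent[p]
    }
    if (p != 0L) path <- c(p, path) else path <- c(root_index(t), path)
    path
  })
  out
}

#' Resample a tree at a fixed node spacing
#'
#' Redistributes nodes so that consecutive nodes along every unbranched
#' section are evenly spaced at approximately `spacing` µm (each section is
#' divided uniformly, with internode distance at most `spacing`, so short
#' sections keep slightly denser nodes and no stub internodes arise).
#' Topological points (root, branch points,
#' terminals) are kept exactly, so branch and termination point counts are
#' unchanged and total length is preserved up to the chordal error of the
#' original polyline. A section shorter than `spacing` collapses to its two
#' endpoints; this is not an error.
#'
#' Radii and `z` are interpolated linearly along the section.
#'
#' @param t a [dtree].
#' @param spacing target internode distance (µm), > 0.
#' @return a [dtree].
#' @export
resample_tree <- function(t, spacing) {
  stopifnot(spacing > 0)
  secs <- tree_sections(t)
  root <- root_index(t)
  # new node store, root first
  nx <- t$x[root]; ny <- t$y[root]; nz <- t$z[root]; nr <- t$r[root]
  nparent <- 0L; ntype <- t$type[root]
  new_index_of <- integer(n_nodes(t))   # old topological point -> new index
  new_index_of[root] <- 1L
  for (sec in secs) {
    pts <- cbind(t$x[sec], t$y[sec], t$z[sec])
    rr <- t$r[sec]
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    len <- cum[length(cum)]
    # uniform subdivision: internode distance len/n <= spacing, so a second
    # resampling pass reproduces the same node positions
    n_sub <- max(1L, ceiling(len / spacing - 1e-9))
    svals <- seq_len(n_sub) * (len / n_sub)
    if (len == 0) svals <- 0   # degenerate zero-length section
    start_new <- new_index_of[sec[1]]
    prev <- start_new
    for (k in seq_along(svals)) {
      s <- svals[k]
      j <- findInterval(s, cum, rightmost.closed = TRUE)
      j <- min(max(j, 1L), length(seg))
      f <- if (seg[j] > 0) (s - cum[j]) / seg[j] else 0
      p <- pts[j, ] + f * (pts[j + 1, ] - pts[j, ])
      r <- rr[j] + f * (rr[j + 1] - rr[j])
      last <- k == length(svals)
      if (last) { p <- pts[nrow(pts), ]; r <- rr[length(rr)] }
      nx <- c(nx, p[1]); ny <- c(ny, p[2]); nz <- c(nz, p[3]); nr <- c(nr, r)
      nparent <- c(nparent, prev)
      ntype <- c(ntype, t$type[sec[length(sec)]])
      prev <- length(nx)
      if (last) new_index_of[sec[length(sec)]] <- prev
    }
  }
  dtree(x = nx, y = ny, z = nz, r = nr, parent = nparent, type = ntype)
}

#' Terminal branches of a tree
#'
#' A terminal branch is the piece of dendrite cable between a termination
#' point and the immediately preceding branch point on its path to the root
#' (for a path graph, where no branch point exists, the single terminal
#' branch starts at the root). There is exactly one terminal branch per
#' termination point.
#'
#' @param t a [dtree].
#' @return data.frame with one row per terminal branch: `tip` (node index),
#'   `start` (branch point or root index), `length` (µm), and a list column
#'   `node_path` (ordered indices from `start` to `tip`).
#' @export
dissect_terminal_branches <- function(t) {
  tips <- which(is_terminal(t))
  bp <- is_branch_point(t)
  len <- segment_lengths(t)
  paths <- lapply(tips, function(tip) {
    path <- tip
    p <- t$parent[tip]
    while (p != 0L && !bp[p]) {
      path <- c(p, path)
      p <- t$parent[p]
    }
    start <- if (p == 0L) root_index(t) else p
    if (path[1] == start) path else c(start, path)
  })
  data.frame(
    tip = tips,
    start = vapply(paths, `[`, integer(1), 1L),
    length = vapply(paths, function(p) sum(len[p[-1]]), numeric(1)),
    node_path = I(paths))
}

#' Remove one terminal branch
#'
#' Deletes all nodes of the terminal branch distal to its start node.
#' Termination-point count drops by exactly one; the branch-point count
#' drops by one when the start node had two children (its remaining child
#' cable becomes a continuation) and is unchanged otherwise.
#'
#' @param t a [dtree].
#' @param tip node index of the branch's termination point.
#' @return a [dtree].
#' @export
remove_terminal_branch <- function(t, tip) {
  tb <- dissect_terminal_branches(t)
  row <- match(tip, tb$tip)
  if (is.na(row)) stop("node ", tip, " is not a termination point")
  drop_nodes(t, tb$node_path[[row]][-1])
}

#' Shorten a terminal branch from its tip
#'
#' Trims `amount` µm of cable from the termination point backwards. If the
#' terminal branch is not longer than `amount` the whole branch is removed
#' (as in the stochastic retraction step of the growth model). Otherwise the
#' new termination point is placed exactly at the trimmed position.
#'
#' @param t a [dtree].
#' @param tip node index of the termination point.
#' @param amount cable length to remove (µm, >= 0).
#' @return a [dtree].
#' @export
shorten_terminal <- function(t, tip, amount) {
  stopifnot(amount >= 0)
  if (amount == 0) return(t)
  tb <- dissect_terminal_branches(t)
  row <- match(tip, tb$tip)
  if (is.na(row)) stop("node ", tip, " is not a termination point")
  path <- tb$node_path[[row]]
  if (tb$length[row] <= amount) return(drop_nodes(t, path[-1]))
  len <- segment_lengths(t)
  # walk back from the tip until `amount` cable is consumed
  rem <- amount
  k <- length(path)
  while (k >= 2L && rem >= len[path[k]] - 1e-12) {
    rem <- rem - len[path[k]]
    k <- k - 1L
  }
  keep_node <- path[k]
  drop <- if (k < length(path)) path[(k + 1L):length(path)] else integer(0)
  if (rem > 1e-12) {
    # move the surviving tip part-way towards its parent
    p <- t$parent[keep_node]
    seg <- len[keep_node]
    f <- rem / seg
    t$x[keep_node] <- t$x[keep_node] + f * (t$x[p] - t$x[keep_node])
    t$y[keep_node] <- t$y[keep_node] + f * (t$y[p] - t$y[keep_node])
    t$z[keep_node] <- t$z[keep_node] + f * (t$z[p] - t$z[keep_node])
  }
  drop_nodes(t, drop)
}
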