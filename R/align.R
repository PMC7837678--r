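#' Find the main branch and align a tree
#'
#' Comb-like proprioceptive dendrites have a main branch (MB) from which all
#' lateral branches sprout. The MB is found with a fixed-point iteration and
#' the whole tree is rigidly rotated so the MB runs vertically (+y) with the
#' root at the origin:
#'
#' 1. Rotate the tree so the tip of the metric-longest root path sits
#'    vertically above the root.
#' 2. Compute the bounding box of the rotated nodes; find the nodes nearest
#'    (2D Euclidean) to the top-left and top-right corners (ties broken by
#'    the lowest node index).
#' 3. The candidate MB tip is the first shared node on the two corner nodes'
#'    root paths, walking tipwards (their deepest common ancestor; when both
#'    corners pick the same node, that node itself).
#' 4. Re-rotate so the candidate tip is vertical and repeat from 2 until the
#'    tip node no longer changes.
#'
#' @param t a [dtree].
#' @param tol alignment tolerance (µm) on |x| of the MB tip (diagnostic; the
#'   exact rotation always satisfies it).
#' @param max_iter maximum number of fixed-point iterations.
#' @return An `aligned_dtree`: list with `tree` (the rotated [dtree], root at
#'   the origin), `mb_node_path` (node indices root -> MB tip),
#'   `mb_tip`, `rotation_angle` (radians, total applied rotation) and
#'   `iterations`.
#' @export
find_main_branch <- function(t, tol = 1, max_iter = 50) {
  rt <- root_index(t)
  t <- translate_tree(t, -t$x[rt], -t$y[rt])
  total_rot <- 0
  align_to <- function(tr, tip) {
    if (tip == rt) return(list(tr = tr, ang = 0))
    # tip sits at clockwise angle atan2(x, y) from +y; rotate CCW by that
    # angle to bring it onto the +y axis
    ang <- atan2(tr$x[tip], tr$y[tip])
    list(tr = rotate_tree(tr, ang), ang = ang)
  }
  # initialisation: tip of the metric-longest path
  pv <- path_distances(t)
  tip <- which.max(pv)
  st <- align_to(t, tip)
  t <- st$tr; total_rot <- total_rot + st$ang
  prev_tip <- tip
  seen <- tip
  for (it in seq_len(max_iter)) {
    xr <- range(t$x); yr <- range(t$y)
    d_tl <- (t$x - xr[1])^2 + (t$y - yr[2])^2
    d_tr <- (t$x - xr[2])^2 + (t$y - yr[2])^2
    n_tl <- which.min(d_tl)   # which.min takes the lowest index on ties
    n_tr <- which.min(d_tr)
    tip <- if (n_tl == n_tr) n_tl else .deepest_common_ancestor(t, n_tl, n_tr)
    if (tip == rt) tip <- prev_tip   # degenerate box: keep previous estimate
    if (tip != prev_tip && tip %in% seen) {
      # oscillation between equally plausible tips: resolve towards the
      # candidate with the longer metric root path (then lowest index)
      cyc <- unique(c(seen[which(seen == tip)[1]:length(seen)], tip))
      tip <- cyc[order(-pv[cyc], cyc)][1]
      prev_tip <- tip
    }
    seen <- c(seen, tip)
    st <- align_to(t, tip)
    t <- st$tr; total_rot <- total_rot + st$ang
    if (tip == prev_tip) {
      out <- structure(
        list(tree = t, mb_node_path = root_path(t, tip), mb_tip = tip,
             rotation_angle = total_rot, iterations = it, tol = tol),
        class = "aligned_dtree")
      if (abs(t$x[tip]) > tol)
        stop("main-branch alignment failed tolerance check")
      return(out)
    }
    prev_tip <- tip
  }
  stop("main-branch search did not converge after ", max_iter,
       " iterations (last tip: ", tip, ")")
}

.deepest_common_ancestor <- function(t, a, b) {
  pa <- root_path(t, a)
  pb <- root_path(t, b)
  k <- min(length(pa), length(pb))
  same <- pa[seq_len(k)] == pb[seq_len(k)]
  pa[max(which(same))]
}

#' @export
print.aligned_dtree <- function(x, ...) {
  cat(sprintf(
    "<aligned_dtree> MB of %d nodes (tip %d), rotation %.1f deg, %d iteration(s)\n",
    length(x$mb_node_path), x$mb_tip, x$rotation_angle * 180 / pi,
    x$iterations))
  print(x$tree)
  invisible(x)
}

#' Per-segment orientation angles of an aligned tree
#'
#' For every non-root node, the orientation of the segment joining it to its
#' parent, measured against the MB (vertical) axis and folded into
#' `[0, 90]` degrees: 0 means the segment runs along the MB (dorsoventral
#' axis), 90 means it runs along the anteroposterior axis, i.e. the
#' direction of body-wall contraction. Folding reflects the orientation
#' (not direction) semantics of the measurement: a segment and its reverse
#' get the same angle, as do mirror images across the MB.
#'
#' Main-branch nodes and zero-length segments get `NA`.
#'
#' @param at an `aligned_dtree` from [find_main_branch()].
#' @return numeric vector of angles in degrees, one per node.
#' @export
segment_orientation_angles <- function(at) {
  t <- at$tree
  p <- t$parent
  ang <- rep(NA_real_, n_nodes(t))
  nz <- which(p > 0L)
  dx <- t$x[nz] - t$x[p[nz]]
  dy <- t$y[nz] - t$y[p[nz]]
  len <- sqrt(dx^2 + dy^2)
  a <- atan2(abs(dx), abs(dy)) * 180 / pi
  a[len == 0] <- NA_real_
  ang[nz] <- a
  ang[at$mb_node_path] <- NA_real_
  ang
}
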