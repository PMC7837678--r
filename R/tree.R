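#' Rooted geometric dendrite trees
#'
#' A `dtree` stores one dendrite reconstruction as parallel node vectors:
#' 3D coordinates and radii in micrometres plus a parent pointer per node.
#' Nodes are kept in topological order (every parent precedes its children),
#' the root has `parent = 0`. Exactly one root is allowed and the parent links
#' must form a connected, cycle-free structure.
#'
#' Analyses treat the trees as planar: `z` is carried through all operations
#' but ignored for spanning areas, orientation angles and growth simulations,
#' matching the flat geometry of body-wall sensory dendrites. Cable lengths
#' use the full 3D Euclidean metric.
#'
#' @param x,y,z numeric node coordinates (µm).
#' @param r numeric node radii (µm).
#' @param parent integer index of each node's parent in the vectors
#'   (0 for the root).
#' @param id optional original node ids (defaults to `1:n`).
#' @param type optional SWC structure-type codes (defaults to 0).
#' @return An object of class `dtree`.
#' @export
dtree <- function(x, y, z = 0, r = 0.1, parent, id = NULL, type = NULL) {
  n <- length(x)
  z <- rep_len(z, n)
  r <- rep_len(r, n)
  if (is.null(id)) id <- seq_len(n)
  if (is.null(type)) type <- rep_len(0L, n)
  stopifnot(length(y) == n, length(parent) == n)
  t <- structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         r = as.numeric(r), parent = as.integer(parent),
         id = as.integer(id), type = as.integer(type)),
    class = "dtree")
  validate_dtree(t)
  reorder_dtree(t)
}

#' @export
print.dtree <- function(x, ...) {
  cat(sprintf(
    "<dtree> %d nodes | %d branch points | %d terminals | L = %.2f um\n",
    n_nodes(x), sum(is_branch_point(x)), sum(is_terminal(x)),
    total_length(x)))
  invisible(x)
}

validate_dtree <- function(t) {
  n <- length(t$x)
  if (n < 1L) stop("dtree must have at least one node")
  root <- which(t$parent == 0L)
  if (length(root) != 1L)
    stop("dtree must have exactly one root, found ", length(root))
  bad <- t$parent < 0L | t$parent > n
  if (any(bad))
    stop("dangling parent reference at node(s) ",
         paste(which(bad), collapse = ", "))
  if (any(t$parent == seq_len(n)))
    stop("node cannot be its own parent")
  # connectivity / acyclicity: every node must reach the root
  depth <- node_depth(t)
  if (anyNA(depth))
    stop("parent links contain a cycle or disconnected component")
  invisible(t)
}

# number of edges from root; NA marks unreachable nodes
node_depth <- function(t) {
  n <- length(t$parent)
  depth <- rep(NA_integer_, n)
  depth[t$parent == 0L] <- 0L
  for (pass in seq_len(n)) {
    known <- !is.na(depth)
    if (all(known)) break
    upd <- !known & t$parent > 0L & !is.na(depth[pmax(t$parent, 1L)])
    if (!any(upd)) break
    depth[upd] <- depth[t$parent[upd]] + 1L
  }
  depth
}

# permute nodes so every parent precedes its children
reorder_dtree <- function(t) {
  depth <- node_depth(t)
  ord <- order(depth, seq_along(depth))
  if (all(ord == seq_along(ord))) return(t)
  inv <- integer(length(ord))
  inv[ord] <- seq_along(ord)
  out <- t
  for (f in c("x", "y", "z", "r", "id", "type")) out[[f]] <- t[[f]][ord]
  pid <- t$parent[ord]
  out$parent <- as.integer(ifelse(pid == 0L, 0L, inv[pmax(pid, 1L)]))
  out
}

#' Basic tree accessors
#'
#' `n_nodes()` counts nodes; `root_index()` returns the root's index;
#' `n_children()` gives the number of children per node; `is_branch_point()`,
#' `is_terminal()` and `is_continuation()` classify nodes (a terminal is a
#' non-root node without children; the root is a branch point only if it has
#' two or more children).
#'
#' @param t a `dtree`.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
n_nodes <- function(t) length(t$x)

#' @rdname tree-accessors
#' @export
root_index <- function(t) which(t$parent == 0L)

#' @rdname tree-accessors
#' @export
n_children <- function(t) {
  tabulate(t$parent[t$parent > 0L], nbins = n_nodes(t))
}

#' @rdname tree-accessors
#' @export
is_branch_point <- function(t) n_children(t) >= 2L

#' @rdname tree-accessors
#' @export
is_terminal <- function(t) n_children(t) == 0L & t$parent != 0L

#' @rdname tree-accessors
#' @export
is_continuation <- function(t) n_children(t) == 1L & t$parent != 0L

#' Segment lengths and cable statistics
#'
#' `segment_lengths()` returns, per node, the 3D Euclidean length of the
#' segment joining it to its parent (0 for the root). `total_length()` sums
#' them; `counts_and_lengths()` returns the branch-point count `N` and total
#' cable length `L` used by the wire-optimality scaling analysis.
#'
#' @param t a `dtree`.
#' @return `counts_and_lengths()`: a list with elements `N` and `L`.
#' @export
segment_lengths <- function(t) {
  p <- t$parent
  len <- numeric(n_nodes(t))
  nz <- p > 0L
  len[nz] <- sqrt((t$x[nz] - t$x[p[nz]])^2 +
                  (t$y[nz] - t$y[p[nz]])^2 +
                  (t$z[nz] - t$z[p[nz]])^2)
  len
}

#' @rdname segment_lengths
#' @export
total_length <- function(t) sum(segment_lengths(t))

#' @rdname segment_lengths
#' @export
counts_and_lengths <- function(t) {
  list(N = sum(is_branch_point(t)), L = total_length(t))
}

#' Path metrics to the root
#'
#' `path_distances()` gives the metric path length from every node to the
#' root; `root_path()` the node indices from root to node `i`;
#' `branch_order()` the topological branch order (0 at the root, +1 after
#' every branch point).
#'
#' @param t a `dtree`.
#' @param i a node index.
#' @export
path_distances <- function(t) {
  len <- segment_lengths(t)
  pvec <- numeric(n_nodes(t))
  # nodes are in topological order, single pass suffices
  for (i in seq_len(n_nodes(t))) {
    p <- t$parent[i]
    pvec[i] <- if (p == 0L) 0 else pvec[p] + len[i]
  }
  pvec
}

#' @rdname path_distances
#' @export
root_path <- function(t, i) {
  path <- integer(0)
  while (i != 0L) {
    path <- c(i, path)
    i <- t$parent[i]
  }
  path
}

#' @rdname path_distances
#' @export
branch_order <- function(t) {
  bp <- is_branch_point(t)
  bo <- integer(n_nodes(t))
  for (i in seq_len(n_nodes(t))) {
    p <- t$parent[i]
    bo[i] <- if (p == 0L) 0L else bo[p] + as.integer(bp[p])
  }
  bo
}

children_list <- function(t) {
  n <- n_nodes(t)
  kids <- vector("list", n)
  idx <- which(t$parent > 0L)
  sp <- split(idx, t$parent[idx])
  kids[as.integer(names(sp))] <- sp
  kids
}

#' Extract a subtree
#'
#' Returns the subtree rooted at node `i` (node `i` becomes the new root)
#' together with the index mapping to the original tree.
#'
#' @param t a `dtree`.
#' @param i index of the new root.
#' @return list with `tree` (a `dtree`) and `nodes` (original indices, in the
#'   subtree's node order).
#' @export
subtree_at <- function(t, i) {
  keep <- descendants_of(t, i)
  map <- integer(n_nodes(t))
  map[keep] <- seq_along(keep)
  parent <- t$parent[keep]
  parent <- ifelse(keep == i, 0L, map[parent])
  sub <- structure(
    list(x = t$x[keep], y = t$y[keep], z = t$z[keep], r = t$r[keep],
         parent = as.integer(parent), id = t$id[keep], type = t$type[keep]),
    class = "dtree")
  list(tree = sub, nodes = keep)
}

# i and all its descendants, in increasing index order
descendants_of <- function(t, i) {
  n <- n_nodes(t)
  keep <- logical(n)
  keep[i] <- TRUE
  if (i < n) for (j in (i + 1L):n) if (keep[t$parent[j]]) keep[j] <- TRUE
  which(keep)
}

#' Drop nodes from a tree
#'
#' Removes the given nodes. Children of removed nodes must themselves be
#' removed (only whole subtrees or distal cable may be dropped); the root
#' cannot be removed.
#'
#' @param t a `dtree`.
#' @param drop integer node indices to remove.
#' @return a `dtree`.
#' @export
drop_nodes <- function(t, drop) {
  if (length(drop) == 0L) return(t)
  keep <- setdiff(seq_len(n_nodes(t)), drop)
  if (any(t$parent[keep] %in% drop))
    stop("cannot drop a node while keeping its children")
  if (root_index(t) %in% drop) stop("cannot drop the root")
  map <- integer(n_nodes(t))
  map[keep] <- seq_along(keep)
  parent <- t$parent[keep]
  parent[parent > 0L] <- map[parent[parent > 0L]]
  structure(
    list(x = t$x[keep], y = t$y[keep], z = t$z[keep], r = t$r[keep],
         parent = as.integer(parent), id = t$id[keep], type = t$type[keep]),
    class = "dtree")
}

#' Rigid 2D transforms
#'
#' Rotate a tree about a point in the x-y plane (counter-clockwise, radians)
#' or translate it. `z` is untouched.
#'
#' @param t a `dtree`.
#' @param angle rotation angle in radians (counter-clockwise).
#' @param centre length-2 numeric, centre of rotation.
#' @param dx,dy translation offsets (µm).
#' @export
rotate_tree <- function(t, angle, centre = c(0, 0)) {
  xs <- t$x - centre[1]; ys <- t$y - centre[2]
  t$x <- centre[1] + xs * cos(angle) - ys * sin(angle)
  t$y <- centre[2] + xs * sin(angle) + ys * cos(angle)
  t
}

#' @rdname rotate_tree
#' @export
translate_tree <- function(t, dx = 0, dy = 0) {
  t$x <- t$x + dx
  t$y <- t$y + dy
  t
}
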