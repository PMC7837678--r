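#' Wire-optimality scaling law
#'
#' For planar dendrites that minimise wire, total cable length L, spanning
#' area S and number of branch points N obey L = sqrt(S * N / pi).
#' `scaling_law_length()` evaluates the law for given S and N.
#'
#' @param S spanning area (µm², >= 0).
#' @param N number of branch points (>= 0).
#' @return predicted total length (µm).
#' @export
scaling_law_length <- function(S, N) {
  stopifnot(all(S >= 0), all(N >= 0))
  sqrt(S * N / pi)
}

#' Greedy minimum spanning tree morphology
#'
#' Connects target points one at a time to a growing tree rooted at `root`.
#' Each step attaches the unconnected target with the smallest combined
#' cost over attachment points P anywhere on the existing cable (segment
#' interiors included):
#' `dist(target, P) + bf * (path_length(P) + dist(target, P))`,
#' i.e. wire cost plus `bf` times the resulting path length from the new
#' node to the root. `bf = 0` is pure wire minimisation; larger `bf` trades
#' wire for shorter root paths. When the best attachment point falls in the
#' interior of a segment, the segment is split there, so interstitial
#' attachments create one branch point each — the construction that gives
#' rise to the wire-optimality scaling law. Ties are broken towards the
#' lowest target index.
#'
#' Targets coinciding with existing cable are skipped (with a message).
#'
#' @param targets numeric matrix (n x 2) of target coordinates (µm).
#' @param root length-2 numeric root position.
#' @param bf balancing factor in `[0, 1]`.
#' @param record if `TRUE`, attach a data.frame (attribute `"record"`) with
#'   one row per connected target: `n_targets`, `N` (branch points), `L`
#'   (total length) and `S` (convex spanning area of the current nodes).
#' @return a [dtree].
#' @export
generate_mst_tree <- function(targets, root = c(0, 0), bf = 0.2,
                              record = FALSE) {
  stopifnot(bf >= 0, bf <= 1)
  targets <- matrix(as.numeric(targets), ncol = 2)
  nt <- nrow(targets)
  stopifnot(nt >= 1)
  eps <- 1e-9
  # node store (root first); one segment per non-root node (to its parent)
  nx <- root[1]; ny <- root[2]
  parent <- 0L
  plen <- 0
  nch <- 0L          # children counts
  n_bp <- 0L
  open <- rep(TRUE, nt)
  # best attachment per open target: squared-free distance, combined cost
  # and the attachment point with the node whose parent segment carries it
  d0 <- sqrt((targets[, 1] - root[1])^2 + (targets[, 2] - root[2])^2)
  best_cost <- d0 + bf * d0
  best_dist <- d0
  best_px <- rep(root[1], nt); best_py <- rep(root[2], nt)
  best_child <- rep(1L, nt)    # 1 = attach at the root node itself
  L <- 0
  rec <- if (record) vector("list", nt) else NULL
  skipped <- 0L

  # locate the current segment containing point P, starting from `child`
  # (splits only ever insert collinear nodes rootwards of child)
  resolve <- function(child, px, py) {
    c0 <- child
    for (guard in 1:1000) {
      a <- parent[c0]
      if (a == 0L) return(list(node = c0, t = 0))
      vx <- nx[c0] - nx[a]; vy <- ny[c0] - ny[a]
      l2 <- vx^2 + vy^2
      tt <- if (l2 > 0) ((px - nx[a]) * vx + (py - ny[a]) * vy) / l2 else 0
      if (tt >= -1e-7) return(list(node = c0, t = min(max(tt, 0), 1)))
      c0 <- a
    }
    stop("attachment resolution failed")
  }

  for (step in seq_len(nt)) {
    oi <- which(open)
    if (length(oi) == 0L) break
    pick <- oi[which.min(best_cost[oi])]
    open[pick] <- FALSE
    if (best_dist[pick] < eps) {
      message("skipping duplicate target ", pick,
              " coincident with existing cable")
      skipped <- skipped + 1L
      next
    }
    # materialise the attachment point
    loc <- resolve(best_child[pick], best_px[pick], best_py[pick])
    att <- loc$node
    if (loc$t > eps && loc$t < 1 - eps) {
      a <- parent[att]
      sx <- nx[a] + loc$t * (nx[att] - nx[a])
      sy <- ny[a] + loc$t * (ny[att] - ny[a])
      nx <- c(nx, sx); ny <- c(ny, sy)
      parent <- c(parent, a)
      plen <- c(plen, plen[a] + sqrt((sx - nx[a])^2 + (sy - ny[a])^2))
      nch <- c(nch, 1L)                 # inherits child `att`
      s <- length(nx)
      parent[att] <- s
      att <- s
    } else if (loc$t <= eps) {
      att <- parent[att]
      if (att == 0L) att <- loc$node    # the root node itself
    }
    nx <- c(nx, targets[pick, 1]); ny <- c(ny, targets[pick, 2])
    parent <- c(parent, att)
    plen <- c(plen, plen[att] + best_dist[pick])
    nch <- c(nch, 0L)
    was <- nch[att]
    nch[att] <- was + 1L
    if (was == 1L) n_bp <- n_bp + 1L
    L <- L + best_dist[pick]
    v <- length(nx)
    # update open targets against the single new cable segment att -> v
    oi <- which(open)
    if (length(oi) > 0L) {
      ax <- nx[att]; ay <- ny[att]
      vx <- nx[v] - ax; vy <- ny[v] - ay
      l2 <- vx^2 + vy^2
      tt <- pmin(pmax(((targets[oi, 1] - ax) * vx +
                       (targets[oi, 2] - ay) * vy) / l2, 0), 1)
      qx <- ax + tt * vx; qy <- ay + tt * vy
      d <- sqrt((targets[oi, 1] - qx)^2 + (targets[oi, 2] - qy)^2)
      cost <- d + bf * (plen[att] + tt * sqrt(l2) + d)
      upd <- cost < best_cost[oi]
      iu <- oi[upd]
      best_cost[iu] <- cost[upd]
      best_dist[iu] <- d[upd]
      best_px[iu] <- qx[upd]; best_py[iu] <- qy[upd]
      best_child[iu] <- v
    }
    if (record)
      rec[[step]] <- c(n_targets = step - skipped, N = n_bp, L = L,
                       S = convex_area(cbind(nx, ny)))
  }
  t <- dtree(x = nx, y = ny, z = 0, r = 0.1, parent = parent)
  if (record) {
    rec <- as.data.frame(do.call(rbind, rec[!vapply(rec, is.null, logical(1))]))
    attr(t, "record") <- rec
  }
  t
}

#' Scale a tree to a target spanning area
#'
#' Isotropic 2D scaling about the root so that the recomputed spanning area
#' equals `target_area`. Because a planar rescale by factor f multiplies any
#' area measure by f^2 exactly, the factor is sqrt(target/original).
#'
#' @param t a [dtree].
#' @param target_area target spanning area (µm², default 100).
#' @param method spanning-area method (see [spanning_area()]).
#' @return a [dtree]; lengths scale by sqrt(target/original).
#' @export
scale_to_area <- function(t, target_area = 100,
                          method = c("concave", "convex")) {
  method <- match.arg(method)
  S <- spanning_area(t, method = method)
  if (S <= 0) stop("tree has degenerate (zero) spanning area")
  f <- sqrt(target_area / S)
  rt <- root_index(t)
  t$x <- t$x[rt] + (t$x - t$x[rt]) * f
  t$y <- t$y[rt] + (t$y - t$y[rt]) * f
  t
}

#' Fit the length vs sqrt(branch points) scaling
#'
#' Ordinary least squares of total length L on sqrt(N) over a table of
#' (N, L) pairs (typically after area normalisation to 100 µm², for which
#' the wire-optimality law predicts slope 10/sqrt(pi)).
#'
#' @param triples data.frame with columns `N` and `L` (>= 3 rows).
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_scaling <- function(triples) {
  stopifnot(nrow(triples) >= 3)
  sN <- sqrt(triples$N)
  if (max(sN) == min(sN)) stop("sqrt(N) is constant; slope undefined")
  fit <- stats::lm(L ~ sN, data = data.frame(L = triples$L, sN = sN))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = nrow(triples))
}

#' MST scaling-law ensemble
#'
#' Repeats the synthetic-tree experiment behind the scaling analysis:
#' uniform random targets on a square region of `area` µm² are connected by
#' [generate_mst_tree()] (root at the region centre), the tree is recorded
#' at every intermediate target count up to `max_targets`, and every
#' recorded (N, L) pair is normalised to the common area by scaling L with
#' sqrt(area / S) (S: convex spanning area at that step). Steps whose point
#' cloud is still area-degenerate (fewer than 3 points or zero branch
#' points) are dropped.
#'
#' @param n_sims number of simulations.
#' @param max_targets targets added per simulation.
#' @param bf balancing factor.
#' @param area sampling region area (µm²).
#' @param seed integer seed.
#' @return data.frame with columns `sim`, `n_targets`, `N`, `L`
#'   (area-normalised), `S` (raw spanning area).
#' @export
mst_scaling_ensemble <- function(n_sims = 100, max_targets = 500, bf = 0.2,
                                 area = 100, seed = 1) {
  set.seed(seed)
  side <- sqrt(area)
  out <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    targets <- cbind(stats::runif(max_targets, 0, side),
                     stats::runif(max_targets, 0, side))
    t <- generate_mst_tree(targets, root = c(side / 2, side / 2), bf = bf,
                           record = TRUE)
    rec <- attr(t, "record")
    # steps with < 2 branch points have essentially one-dimensional
    # spanning fields; their area normalisation is degenerate
    rec <- rec[rec$S > 0 & rec$N >= 2, , drop = FALSE]
    rec$L <- rec$L * sqrt(area / rec$S)
    rec$sim <- s
    out[[s]] <- rec
  }
  do.call(rbind, out)
}
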