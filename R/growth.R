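#' Growth-model parameters
#'
#' Bundles all constants of the iterative stochastic growth model with
#' timed stochastic retraction. Times are hours AEL, lengths µm; one
#' growth iteration represents 15 minutes.
#'
#' @param b_r mean branch additions per 15-min iteration. The default of
#'   12 additions per iteration brings simulated trees to the peak
#'   branch-point counts observed in embryonic reconstructions (roughly
#'   50-60) by the end of the extension phase; note that an addition often
#'   extends an existing branch tip, so branch points accrue at roughly a
#'   third of the addition rate.
#' @param r_grow_pre maximal growth-range radius before `t_switch` (µm).
#' @param r_grow_post growth-range radius after `t_switch` (µm).
#' @param k target-selection noise in `[0, 1]`: 0 = uniform choice among
#'   candidate targets, values towards 1 increasingly prefer targets far
#'   from the existing tree (selection probability proportional to
#'   d^(k/(1-k)), capped distances).
#' @param bf balancing factor of the attachment cost (wire + bf * root
#'   path length).
#' @param n_probe random target points probed per iteration.
#' @param retraction_times times (h AEL) at which a retraction step runs.
#' @param bins data.frame with per-bin retraction parameters: `bin_end`
#'   (right edge, h AEL), `shorten_fraction` (fraction of terminals whose
#'   tips are shortened: combined retracting + shortening class fraction),
#'   `new_fraction` (fraction of new branches added), `shorten_length`
#'   (cable removed per selected tip, µm; mean length of retracted
#'   branches).
#' @param t_start,t_switch,t_stop simulation start, growth-radius switch
#'   (end of the pre-retraction growth regime) and stop times (h AEL).
#' @param attach_spacing node spacing (µm) at which grown cable is
#'   subdivided; candidate attachment points are the tree nodes at this
#'   resolution.
#' @param poisson draw per-iteration additions as Poisson(`b_r`) (default);
#'   otherwise use deterministic rounding.
#' @return object of class `growth_params` (a validated list).
#' @export
growth_params <- function(b_r = 12,
                          r_grow_pre = 2.5,
                          r_grow_post = 1.81,
                          k = 0.5,
                          bf = 0.2,
                          n_probe = 100000,
                          retraction_times = seq(16.5, 21.5, by = 1),
                          bins = data.frame(
                            bin_end = c(17.5, 18.5, 19.5, 20.5, 21.5),
                            shorten_fraction = c(0.50, 0.50, 0.45, 0.30, 0.15),
                            new_fraction = c(0.25, 0.20, 0.12, 0.06, 0.02),
                            shorten_length = c(2.5, 2.5, 2.5, 2.5, 2.5)),
                          t_start = 16, t_switch = 19.5, t_stop = 22.5,
                          attach_spacing = 0.5,
                          poisson = TRUE) {
  stopifnot(b_r >= 0, r_grow_pre > 0, r_grow_post > 0,
            k >= 0, k <= 1, bf >= 0, bf <= 1, n_probe >= 1,
            attach_spacing > 0, t_start < t_stop,
            all(bins$shorten_fraction >= 0 & bins$shorten_fraction <= 1),
            all(bins$new_fraction >= 0 & bins$new_fraction <= 1),
            all(bins$shorten_length > 0))
  structure(list(b_r = b_r, r_grow_pre = r_grow_pre,
                 r_grow_post = r_grow_post, k = k, bf = bf,
                 n_probe = n_probe, retraction_times = retraction_times,
                 bins = bins, t_start = t_start, t_switch = t_switch,
                 t_stop = t_stop, attach_spacing = attach_spacing,
                 poisson = poisson),
            class = "growth_params")
}

#' Growth arena
#'
#' The 2D region in which a simulation runs: an initial main branch and
#' the contour polygon of the dendritic spanning field (tight boundary,
#' shrink factor 1, of a reference morphology). All main-branch nodes
#' must lie inside (or on) the contour.
#'
#' @param mb a [dtree]: the initial main branch (typically a path).
#' @param contour two-column matrix tracing the arena polygon.
#' @return object of class `growth_arena`.
#' @export
growth_arena <- function(mb, contour) {
  contour <- as.matrix(contour)
  stopifnot(inherits(mb, "dtree"), ncol(contour) == 2, nrow(contour) >= 3)
  if (!all(points_in_polygon(cbind(mb$x, mb$y), contour)))
    stop("main branch must lie inside the arena contour")
  structure(list(mb = mb, contour = contour), class = "growth_arena")
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' Points within `tol` of a polygon edge count as inside, so that nodes
#' interpolated along a boundary edge are not rejected by floating-point
#' round-off.
#'
#' @param pts two-column matrix of points.
#' @param poly two-column polygon matrix.
#' @param tol boundary tolerance (µm).
#' @return logical vector.
#' @export
points_in_polygon <- function(pts, poly, tol = 1e-6) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  inside <- .pip_crossing(pts[, 1], pts[, 2], poly)
  miss <- which(!inside)
  if (length(miss) > 0L && tol > 0) {
    ax <- poly[, 1]; ay <- poly[, 2]
    bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
    ex <- bx - ax; ey <- by - ay
    el2 <- pmax(ex^2 + ey^2, 1e-300)
    for (i in miss) {
      tproj <- pmin(pmax(((pts[i, 1] - ax) * ex + (pts[i, 2] - ay) * ey) /
                           el2, 0), 1)
      d2 <- (pts[i, 1] - ax - tproj * ex)^2 + (pts[i, 2] - ay - tproj * ey)^2
      if (min(d2) <= tol^2) inside[i] <- TRUE
    }
  }
  inside
}

# vectorised crossing-number (even-odd) point-in-polygon test
.pip_crossing <- function(px, py, poly) {
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- rep(FALSE, length(px))
  for (e in seq_along(x1)) {
    if (y1[e] == y2[e]) next
    idx <- which((y1[e] > py) != (y2[e] > py))
    if (length(idx) == 0L) next
    xint <- x1[e] + (py[idx] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
    sel <- idx[xint > px[idx]]
    inside[sel] <- !inside[sel]
  }
  inside
}

# uniform samples inside a polygon (rejection from the bounding box)
sample_in_polygon <- function(n, poly) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(numeric(0), 0, 2)
  guard <- 0L
  while (nrow(out) < n && guard < 60L) {
    guard <- guard + 1L
    m <- max(2L * (n - nrow(out)), 100L)
    cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
    keep <- points_in_polygon(cand, poly, tol = 0)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  if (nrow(out) < n) stop("degenerate arena: cannot sample inside contour")
  out[seq_len(n), , drop = FALSE]
}

# internal growth state: dtree plus cached root-path lengths and the
# protected main-branch node count
.grow_state <- function(tree, n_mb) {
  list(tree = tree, plen = path_distances(tree), n_mb = n_mb)
}

# add one branch towards a chosen target; returns updated state
.attach_target <- function(st, target, p, radius, contour) {
  t <- st$tree
  d <- sqrt((t$x - target[1])^2 + (t$y - target[2])^2)
  cost <- d + p$bf * (st$plen + d)
  v <- which.min(cost)            # lowest index on ties
  seg_len <- min(d[v], radius)
  if (seg_len < 1e-9) return(st)
  dir <- c(target[1] - t$x[v], target[2] - t$y[v]) / d[v]
  n_pts <- max(1L, ceiling(seg_len / p$attach_spacing))
  s <- seq_len(n_pts) / n_pts * seg_len
  px <- t$x[v] + dir[1] * s
  py <- t$y[v] + dir[2] * s
  inside <- points_in_polygon(cbind(px, py), contour)
  n_keep <- if (all(inside)) n_pts else (which(!inside)[1] - 1L)
  if (n_keep < 1L) return(st)
  n0 <- n_nodes(t)
  t$x <- c(t$x, px[seq_len(n_keep)])
  t$y <- c(t$y, py[seq_len(n_keep)])
  t$z <- c(t$z, rep(t$z[v], n_keep))
  t$r <- c(t$r, rep(t$r[v], n_keep))
  t$type <- c(t$type, rep(t$type[v], n_keep))
  t$parent <- c(t$parent, c(v, n0 + seq_len(n_keep - 1L)))
  st$tree <- t
  st$plen <- c(st$plen, st$plen[v] + s[seq_len(n_keep)])
  st
}

#' One growth iteration
#'
#' Probes the arena with `n_probe` uniform random target points, measures
#' each point's shortest Euclidean distance to the tree (capped at the
#' active growth radius), selects a target at random with preference for
#' larger capped distances (noise parameter `k`), and connects it to the
#' tree at the node minimising wire plus `bf` times root-path cost; new
#' cable is laid in the direction of the target, never longer than the
#' growth radius and never outside the contour. This is repeated for the
#' iteration's number of branch additions (Poisson(`b_r`) by default).
#'
#' @param state a [dtree] (or internal growth state).
#' @param arena a [growth_arena].
#' @param p a [growth_params].
#' @param radius active growth-range radius (µm).
#' @param n_add number of additions; default draws Poisson(`b_r`).
#' @return a [dtree] (when called with a [dtree]) or internal state.
#' @export
grow_step <- function(state, arena, p, radius = p$r_grow_pre,
                      n_add = NULL) {
  plain <- inherits(state, "dtree")
  st <- if (plain) .grow_state(state, n_nodes(state)) else state
  if (is.null(n_add))
    n_add <- if (p$poisson) stats::rpois(1, p$b_r) else round(p$b_r)
  if (n_add < 1L) return(if (plain) st$tree else st)
  probes <- sample_in_polygon(p$n_probe, arena$contour)
  # chunked min distance probe -> tree, then incremental updates
  dmin <- rep(Inf, nrow(probes))
  upd_dmin <- function(dmin, X, nodes_x, nodes_y) {
    n <- length(nodes_x)
    nd <- rbind(nodes_x, nodes_y)
    n2 <- nodes_x^2 + nodes_y^2
    chunk <- max(1L, floor(4e6 / max(n, 1L)))
    i <- 1L
    while (i <= nrow(X)) {
      j <- min(i + chunk - 1L, nrow(X))
      Xc <- X[i:j, , drop = FALSE]
      d2 <- rowSums(Xc^2) + rep(1, nrow(Xc)) %o% n2 - 2 * (Xc %*% nd)
      best <- max.col(-d2, ties.method = "first")
      dmin[i:j] <- pmin(dmin[i:j],
                        sqrt(pmax(d2[cbind(seq_len(nrow(Xc)), best)], 0)))
      i <- j + 1L
    }
    dmin
  }
  dmin <- upd_dmin(dmin, probes, st$tree$x, st$tree$y)
  gamma <- if (p$k >= 1) Inf else p$k / (1 - p$k)
  for (a in seq_len(n_add)) {
    d <- pmin(dmin, radius)
    cand <- which(d > 1e-9)
    if (length(cand) == 0L) break
    pick <- if (length(cand) == 1L) cand else if (is.infinite(gamma))
      cand[which.max(d[cand])]
    else if (gamma == 0) sample(cand, 1L)
    else sample(cand, 1L, prob = d[cand]^gamma)
    n_before <- n_nodes(st$tree)
    st <- .attach_target(st, probes[pick, ], p, radius, arena$contour)
    n_after <- n_nodes(st$tree)
    if (n_after > n_before) {
      new <- (n_before + 1L):n_after
      dmin <- upd_dmin(dmin, probes, st$tree$x[new], st$tree$y[new])
    }
  }
  if (plain) st$tree else st
}

#' One stochastic retraction step
#'
#' Selects a uniform random fraction of terminal branches (main-branch tip
#' excluded) and shortens each selected tip by the bin's retraction
#' length; branches not longer than that are removed entirely. Afterwards
#' a fraction of new branches (relative to the pre-step terminal count) is
#' added through the growth machinery. Fractions are converted to counts
#' by round-half-up with a minimum of one branch when the fraction is
#' positive and terminals exist.
#'
#' @param state a [dtree] (or internal growth state).
#' @param arena a [growth_arena].
#' @param p a [growth_params].
#' @param bin one row of `p$bins`.
#' @param radius active growth radius for the added branches.
#' @return same class as `state`.
#' @export
retraction_step <- function(state, arena, p, bin, radius = p$r_grow_post) {
  plain <- inherits(state, "dtree")
  # a bare dtree carries no record of its main branch: every terminal is
  # eligible (the protected-MB bookkeeping lives in simulate_development)
  st <- if (plain) .grow_state(state, 0L) else state
  round_up <- function(x) floor(x + 0.5)
  tb <- dissect_terminal_branches(st$tree)
  tb <- tb[tb$tip > st$n_mb, , drop = FALSE]   # never retract the MB
  n_term <- nrow(tb)
  n_shorten <- round_up(bin$shorten_fraction * n_term)
  if (bin$shorten_fraction > 0 && n_term > 0L) n_shorten <- max(1L, n_shorten)
  if (n_shorten > 0L && n_term > 0L) {
    sel <- sample.int(n_term, min(n_shorten, n_term))
    # terminal branches are node-disjoint distal to their start nodes, so
    # all trims can be planned on the same tree and applied in one pass
    tree <- st$tree
    seg <- segment_lengths(tree)
    drop <- integer(0)
    for (i in sel) {
      path <- tb$node_path[[i]]
      if (tb$length[i] <= bin$shorten_length) {
        drop <- c(drop, path[-1])
        next
      }
      rem <- bin$shorten_length
      k <- length(path)
      while (k >= 2L && rem >= seg[path[k]] - 1e-12) {
        rem <- rem - seg[path[k]]
        k <- k - 1L
      }
      if (k < length(path)) drop <- c(drop, path[(k + 1L):length(path)])
      if (rem > 1e-12 && k >= 2L) {
        keep_node <- path[k]
        pn <- tree$parent[keep_node]
        f <- rem / seg[keep_node]
        tree$x[keep_node] <- tree$x[keep_node] + f * (tree$x[pn] - tree$x[keep_node])
        tree$y[keep_node] <- tree$y[keep_node] + f * (tree$y[pn] - tree$y[keep_node])
        tree$z[keep_node] <- tree$z[keep_node] + f * (tree$z[pn] - tree$z[keep_node])
      }
    }
    tree <- drop_nodes(tree, unique(drop))
    st <- .grow_state(tree, st$n_mb)
  }
  n_new <- round_up(bin$new_fraction * n_term)
  if (bin$new_fraction > 0 && n_term > 0L) n_new <- max(1L, n_new)
  if (n_new > 0L) st <- grow_step(st, arena, p, radius = radius,
                                  n_add = n_new)
  if (plain) st$tree else st
}

#' Simulate dendrite development
#'
#' Runs the full growth model: starting from the arena's main branch at
#' `t_start`, one growth iteration per 15 minutes, with the stochastic
#' retraction step applied after the growth iterations of each time in
#' `retraction_times`. With retraction enabled, the `b_r` growth
#' iterations stop at `t_switch` (the end of the extension phase); later
#' branch additions come only from the retraction steps' new-branch
#' fractions, laid with the post-switch growth radius `r_grow_post`.
#' Without retraction (empty `retraction_times`) growth continues to
#' `t_stop`, which reduces the simulator to the pure growth model.
#'
#' @param arena a [growth_arena].
#' @param p a [growth_params].
#' @param seed integer seed; seeded runs are bit-reproducible.
#' @param keep_frames `"hourly"` (default: frames on whole half-hours) or
#'   `"all"` (every 15-min iteration).
#' @return list with `times` (h AEL) and `trees` (list of [dtree]s), the
#'   first frame being the initial main branch at `t_start`.
#' @export
simulate_development <- function(arena, p, seed = 1,
                                 keep_frames = c("all", "hourly")) {
  keep_frames <- match.arg(keep_frames)
  set.seed(seed)
  mb <- resample_tree(arena$mb, p$attach_spacing)
  st <- .grow_state(mb, n_nodes(mb))
  times <- seq(p$t_start + 0.25, p$t_stop, by = 0.25)
  out_t <- p$t_start
  out_trees <- list(st$tree)
  with_retraction <- length(p$retraction_times) > 0L
  for (tm in times) {
    radius <- if (tm <= p$t_switch) p$r_grow_pre else p$r_grow_post
    if (!with_retraction || tm <= p$t_switch + 1e-9)
      st <- grow_step(st, arena, p, radius = radius)
    if (any(abs(p$retraction_times - tm) < 1e-9)) {
      b <- findInterval(tm, p$bins$bin_end, left.open = TRUE) + 1L
      b <- min(b, nrow(p$bins))
      st <- retraction_step(st, arena, p, p$bins[b, ], radius = radius)
    }
    if (keep_frames == "all" || abs(tm %% 0.5) < 1e-9) {
      out_t <- c(out_t, tm)
      out_trees[[length(out_trees) + 1L]] <- st$tree
    }
  }
  list(times = out_t, trees = out_trees, params = p, seed = seed)
}

#' Extract growth-model parameters from tracked data
#'
#' Parameterises the growth model directly from a time series and its
#' single-branch tracking events, with no fitting: the branch rate `b_r`
#' is the combined rate of newly formed and elongating branches per
#' 15 minutes up to `t_switch` (a model addition realises as either an
#' interstitial branch or a tip elongation, so both event classes count
#' towards the addition rate); per-bin shorten fractions combine the
#' retracting and shortening class fractions; new fractions are the
#' newly-formed class fractions; shorten lengths are the mean lengths of
#' retracted branches per bin; and the growth radii are the mean lengths
#' of newly formed branches before and after `t_switch`.
#'
#' @param series list with `trees` and `times` (see [track_series()]).
#' @param events branch events from [track_series()].
#' @param bin_edges retraction bin edges (right edges, h AEL).
#' @param t_switch pre/post boundary for the growth radii (h AEL).
#' @param ... further arguments passed to [growth_params()].
#' @return a [growth_params].
#' @export
extract_growth_parameters <- function(series, events,
                                      bin_edges = c(17.5, 18.5, 19.5,
                                                    20.5, 21.5),
                                      t_switch = 19.5, ...) {
  tt <- series$times
  pre_hours <- max(tt[tt <= t_switch + 1e-9]) - tt[1]
  if (pre_hours <= 0) stop("series does not cover the extension phase")
  n_add <- sum(events$class %in% c("new", "elongated") &
                 events$t1 <= t_switch + 1e-9)
  b_r <- n_add / (pre_hours * 4)
  summ <- dynamics_summary(events, bin_edges = bin_edges)
  missing_bins <- setdiff(bin_edges, summ$bin_end)
  if (length(missing_bins) > 0L)
    stop("no events in bin(s) ending at: ",
         paste(missing_bins, collapse = ", "))
  shorten_len <- summ$mean_retracted_length
  shorten_len[is.na(shorten_len)] <- mean(shorten_len, na.rm = TRUE)
  new_len <- events$delta_length[events$class == "new"]
  pre_new <- events$t1[events$class == "new"] <= t_switch + 1e-9
  r_pre <- if (any(pre_new)) mean(new_len[pre_new]) else NA_real_
  r_post <- if (any(!pre_new)) mean(new_len[!pre_new]) else r_pre
  if (is.na(r_post)) r_post <- r_pre
  growth_params(
    b_r = b_r,
    r_grow_pre = r_pre,
    r_grow_post = r_post,
    bins = data.frame(
      bin_end = summ$bin_end,
      shorten_fraction = summ$frac_retracted + summ$frac_shortened,
      new_fraction = summ$frac_new,
      shorten_length = shorten_len),
    t_switch = t_switch, ...)
}
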