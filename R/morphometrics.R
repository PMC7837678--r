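#' The 49 branching statistics of a dendrite
#'
#' Computes the full morphometric characterisation used to compare real,
#' retraction-simulated and model-grown dendrites: counts and topological
#' orders, Van Pelt partition asymmetry, cable lengths, diameters, membrane
#' surface and volume, isoneuronal distances of terminals, Euclidean and
#' path distances with compactness, per-branch tortuosity, branching
#' angles, spanning-field statistics (area, cable density, space filling,
#' bounding box), main-branch ratio, terminal statistics, lateral-branch
#' perpendicularity and length statistics, diameter/length extremes, and
#' the total length after normalising the spanning area to 100 µm².
#'
#' Statistics that are undefined for a given topology (e.g. the asymmetry
#' spread of a tree with fewer than two branch points, or lateral-branch
#' statistics of a branchless path) are reported as `NA` rather than
#' raising an error.
#'
#' @param t a [dtree] with radii.
#' @param aligned optionally a precomputed `aligned_dtree` for `t`.
#' @param mesh mesh resolution (µm) of the space-filling statistic.
#' @param area_method spanning-area method, `"concave"` (tight boundary,
#'   shrink 1) or `"convex"`.
#' @return named numeric vector of length 49.
#' @export
compute_morphometrics <- function(t, aligned = NULL, mesh = 1,
                                  area_method = "concave") {
  if (is.null(aligned)) aligned <- find_main_branch(t)
  ta <- aligned$tree                 # same geometry up to rigid motion
  seg <- segment_lengths(ta)
  bo <- branch_order(ta)
  bp <- which(is_branch_point(ta))
  tips <- which(is_terminal(ta))
  eucl <- sqrt((ta$x - ta$x[root_index(ta)])^2 +
               (ta$y - ta$y[root_index(ta)])^2 +
               (ta$z - ta$z[root_index(ta)])^2)
  pv <- path_distances(ta)
  D <- 2 * ta$r
  kids <- children_list(ta)

  sd0 <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)
  mean0 <- function(x) if (length(x) == 0L) NA_real_ else mean(x)

  # Van Pelt partition asymmetry per branch point
  n_tips_below <- integer(n_nodes(ta))
  for (v in rev(seq_len(n_nodes(ta)))) {
    ch <- kids[[v]]
    n_tips_below[v] <- if (is.null(ch) || length(ch) == 0L) 1L
                       else sum(n_tips_below[ch])
  }
  asym <- vapply(bp, function(v) {
    ch <- kids[[v]]
    prs <- utils::combn(ch, 2)
    mean(apply(prs, 2, function(p) {
      r <- n_tips_below[p[1]]; s <- n_tips_below[p[2]]
      if (r + s > 2L) abs(r - s) / (r + s - 2L) else 0
    }))
  }, numeric(1))

  # diameter taper ratios daughter/parent at branch points
  taper <- unlist(lapply(bp, function(v) {
    if (D[v] > 0) D[kids[[v]]] / D[v] else numeric(0)
  }))

  # isoneuronal distances: tips vs nodes off their root path
  iso_mean <- iso_min <- rep(NA_real_, length(tips))
  if (length(tips) > 0L) {
    for (i in seq_along(tips)) {
      off <- setdiff(seq_len(n_nodes(ta)), root_path(ta, tips[i]))
      if (length(off) == 0L) next
      d <- sqrt((ta$x[off] - ta$x[tips[i]])^2 +
                (ta$y[off] - ta$y[tips[i]])^2 +
                (ta$z[off] - ta$z[tips[i]])^2)
      iso_mean[i] <- mean(d)
      iso_min[i] <- min(d)
    }
  }

  # tortuosity over the whole-tree branch length order decomposition
  dec <- blo_decompose(ta, root_index(ta))
  tort <- mapply(function(p, l) {
    e <- sqrt((ta$x[p[length(p)]] - ta$x[p[1]])^2 +
              (ta$y[p[length(p)]] - ta$y[p[1]])^2 +
              (ta$z[p[length(p)]] - ta$z[p[1]])^2)
    if (e > 0) l / e else NA_real_
  }, dec$branches$node_path, dec$branches$length)
  tort <- tort[!is.na(tort)]

  # branching angle between daughters within the branching plane
  bang <- unlist(lapply(bp, function(v) {
    ch <- kids[[v]]
    prs <- utils::combn(ch, 2)
    apply(prs, 2, function(p) {
      u <- c(ta$x[p[1]] - ta$x[v], ta$y[p[1]] - ta$y[v], ta$z[p[1]] - ta$z[v])
      w <- c(ta$x[p[2]] - ta$x[v], ta$y[p[2]] - ta$y[v], ta$z[p[2]] - ta$z[v])
      nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
      if (nu == 0 || nw == 0) return(NA_real_)
      acos(pmin(pmax(sum(u * w) / (nu * nw), -1), 1)) * 180 / pi
    })
  }))
  bang <- bang[!is.na(bang)]

  S <- spanning_area(ta, method = area_method)
  L <- sum(seg)
  width <- diff(range(ta$x))
  height <- diff(range(ta$y))
  mb_len <- sum(seg[aligned$mb_node_path[-1]])

  br <- branch_table(aligned)
  lat_ang <- unlist(br$segment_angles)
  lat_ang <- lat_ang[!is.na(lat_ang)]

  ratios <- D[seg > 0] / seg[seg > 0]

  c(n_branch_points = length(bp),
    max_branch_order = max(bo),
    mean_branch_order = mean(bo),
    sd_branch_order = sd0(bo),
    min_branch_order_terminals = if (length(tips)) min(bo[tips]) else NA_real_,
    mean_branch_order_terminals = mean0(bo[tips]),
    sd_branch_order_terminals = sd0(bo[tips]),
    mean_van_pelt_asymmetry = mean0(asym),
    sd_van_pelt_asymmetry = sd0(asym),
    total_length = L,
    mean_diameter = mean(D),
    sd_diameter = sd0(D),
    mean_taper_ratio = mean0(taper),
    sd_taper_ratio = sd0(taper),
    total_surface = sum(pi * D * seg),
    total_volume = sum(pi * (D / 2)^2 * seg),
    mean_isoneuronal_distance = mean0(iso_mean[!is.na(iso_mean)]),
    min_isoneuronal_distance = mean0(iso_min[!is.na(iso_min)]),
    max_euclidean_distance = max(eucl),
    mean_euclidean_distance = mean(eucl),
    sd_euclidean_distance = sd0(eucl),
    mean_euclidean_compactness = mean(eucl / (bo + 1)),
    sd_euclidean_compactness = sd0(eucl / (bo + 1)),
    max_path_distance = max(pv),
    mean_path_distance = mean(pv),
    sd_path_distance = sd0(pv),
    mean_path_compactness = mean(pv / (bo + 1)),
    sd_path_compactness = sd0(pv / (bo + 1)),
    mean_tortuosity = mean0(tort),
    sd_tortuosity = sd0(tort),
    mean_branching_angle = mean0(bang),
    sd_branching_angle = sd0(bang),
    spanning_area = S,
    cable_density = if (S > 0) L / S else NA_real_,
    space_filling = space_filling(ta, mesh = mesh),
    field_width = width,
    field_height = height,
    field_ratio = if (height > 0) width / height else NA_real_,
    mb_ratio = if (height > 0) mb_len / height else NA_real_,
    n_terminals = length(tips),
    terminal_lateral_density = if (height > 0)
      length(tips) / (height / 2) else NA_real_,
    perpendicularity = mean0(lat_ang),
    min_branch_length = if (nrow(br)) min(br$length) else NA_real_,
    mean_branch_length = if (nrow(br)) mean(br$length) else NA_real_,
    sd_branch_length = sd0(br$length),
    max_branch_length = if (nrow(br)) max(br$length) else NA_real_,
    diameter_length_ratio_min = if (length(ratios)) min(ratios) else NA_real_,
    diameter_length_ratio_max = if (length(ratios)) max(ratios) else NA_real_,
    scaled_length = if (S > 0) L * sqrt(100 / S) else NA_real_)
}

#' Space-filling statistic
#'
#' Coverage efficiency of the spanning field: the fraction of `mesh`-sized
#' grid cells inside the tight boundary of the tree that contain dendritic
#' cable. The cable is internally resampled at half the mesh size so that
#' every crossed cell is marked.
#'
#' @param t a [dtree].
#' @param mesh grid resolution in µm.
#' @return fraction in `[0, 1]`, or `NA` for degenerate (area-free) trees.
#' @export
space_filling <- function(t, mesh = 1) {
  tb <- tight_boundary(cbind(t$x, t$y))
  if (is.null(tb$polygon) || tb$area <= 0) return(NA_real_)
  gx <- seq(min(t$x) + mesh / 2, max(t$x), by = mesh)
  gy <- seq(min(t$y) + mesh / 2, max(t$y), by = mesh)
  if (length(gx) == 0L || length(gy) == 0L) return(NA_real_)
  grid <- expand.grid(x = gx, y = gy)
  inside <- points_in_polygon(cbind(grid$x, grid$y), tb$polygon)
  n_in <- sum(inside)
  if (n_in == 0L) return(NA_real_)
  tr <- resample_tree(t, mesh / 2)
  cell <- unique(paste(floor((tr$x - min(t$x)) / mesh),
                       floor((tr$y - min(t$y)) / mesh)))
  gcell <- paste(floor((grid$x[inside] - min(t$x)) / mesh),
                 floor((grid$y[inside] - min(t$y)) / mesh))
  sum(gcell %in% cell) / n_in
}

#' Morphometric table for a set of trees
#'
#' @param trees list of [dtree] objects.
#' @param ... passed to [compute_morphometrics()].
#' @return data.frame, one row per tree, 49 named columns.
#' @export
morphometric_table <- function(trees, ...) {
  rows <- lapply(trees, compute_morphometrics, ...)
  as.data.frame(do.call(rbind, rows))
}
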