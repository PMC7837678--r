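# Planar geometry: Delaunay triangulation, tight (concave) boundaries and
# spanning areas of dendrite node clouds.

#' Delaunay triangulation of 2D points
#'
#' Incremental Bowyer-Watson triangulation. Intended for the moderate point
#' counts of dendrite reconstructions (hundreds to a few thousand nodes).
#' Exactly degenerate inputs (duplicated or collinear points, frequent in
#' resampled straight cable) are stabilised by an infinitesimal deterministic
#' perturbation that does not affect areas at the reported precision.
#'
#' @param pts numeric matrix with two columns (x, y).
#' @return list with `tri` (m x 3 integer matrix of point indices),
#'   `circumradius` (length m) and `area` (signed-free triangle areas).
#' @export
delaunay2d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) return(list(tri = matrix(integer(0), 0, 3),
                          circumradius = numeric(0), area = numeric(0)))
  scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-9)
  # deterministic symmetry-breaking perturbation
  jit <- 1e-9 * scale
  work <- pts
  work[, 1] <- work[, 1] + jit * sin(seq_len(n) * 12.9898)
  work[, 2] <- work[, 2] + jit * sin(seq_len(n) * 78.2331)

  cx <- mean(range(work[, 1])); cy <- mean(range(work[, 2]))
  r <- scale * 20
  sx <- c(cx - 2 * r, cx + 2 * r, cx)
  sy <- c(cy - r, cy - r, cy + 2 * r)
  px <- c(work[, 1], sx)
  py <- c(work[, 2], sy)
  sup <- n + 1:3

  # triangle store (grown geometrically)
  cap <- max(64L, 8L * n)
  tri <- matrix(NA_integer_, cap, 3)
  ccx <- ccy <- cr2 <- rep(NA_real_, cap)
  alive <- logical(cap)
  m <- 0L
  add_tri <- function(a, b, c) {
    if (m + 1L > cap) {
      cap2 <- cap * 2L
      tri2 <- matrix(NA_integer_, cap2, 3); tri2[1:cap, ] <- tri
      tri <<- tri2
      ccx <<- c(ccx, rep(NA_real_, cap)); ccy <<- c(ccy, rep(NA_real_, cap))
      cr2 <<- c(cr2, rep(NA_real_, cap)); alive <<- c(alive, logical(cap))
      cap <<- cap2
    }
    m <<- m + 1L
    tri[m, ] <<- c(a, b, c)
    ax <- px[a]; ay <- py[a]; bx <- px[b]; by <- py[b]; cxx <- px[c]; cyy <- py[c]
    d <- 2 * (ax * (by - cyy) + bx * (cyy - ay) + cxx * (ay - by))
    if (abs(d) < 1e-300) d <- 1e-300
    ux <- ((ax^2 + ay^2) * (by - cyy) + (bx^2 + by^2) * (cyy - ay) +
           (cxx^2 + cyy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cxx - bx) + (bx^2 + by^2) * (ax - cxx) +
           (cxx^2 + cyy^2) * (bx - ax)) / d
    ccx[m] <<- ux; ccy[m] <<- uy
    cr2[m] <<- (ux - ax)^2 + (uy - ay)^2
    alive[m] <<- TRUE
  }
  add_tri(sup[1], sup[2], sup[3])

  for (i in seq_len(n)) {
    ai <- which(alive[seq_len(m)])
    bad <- ai[(px[i] - ccx[ai])^2 + (py[i] - ccy[ai])^2 <= cr2[ai] *
                (1 + 1e-12)]
    if (length(bad) == 0L) next   # cannot happen for points inside the super-triangle
    alive[bad] <- FALSE
    # boundary of the cavity: edges used exactly once among bad triangles
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- key %in% names(which(table(key) == 1L))
    for (j in which(once)) add_tri(e[j, 1], e[j, 2], i)
  }
  ai <- which(alive[seq_len(m)])
  keep <- ai[rowSums(matrix(tri[ai, ] %in% sup, ncol = 3)) == 0L]
  T <- tri[keep, , drop = FALSE]
  # recompute geometry on the *unperturbed* points
  ax <- pts[T[, 1], 1]; ay <- pts[T[, 1], 2]
  bx <- pts[T[, 2], 1]; by <- pts[T[, 2], 2]
  cx2 <- pts[T[, 3], 1]; cy2 <- pts[T[, 3], 2]
  area <- abs((bx - ax) * (cy2 - ay) - (cx2 - ax) * (by - ay)) / 2
  la <- sqrt((bx - cx2)^2 + (by - cy2)^2)
  lb <- sqrt((ax - cx2)^2 + (ay - cy2)^2)
  lc <- sqrt((ax - bx)^2 + (ay - by)^2)
  crad <- ifelse(area > 1e-300, la * lb * lc / (4 * area), Inf)
  list(tri = T, circumradius = crad, area = area)
}

# union-find connectivity over kept triangles sharing an edge
.tris_connected <- function(T, keep) {
  kt <- which(keep)
  if (length(kt) <= 1L) return(TRUE)
  e <- rbind(cbind(T[kt, 1], T[kt, 2], kt),
             cbind(T[kt, 2], T[kt, 3], kt),
             cbind(T[kt, 3], T[kt, 1], kt))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sp <- split(e[, 3], key)
  parent <- seq_len(max(kt))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (grp in sp) if (length(grp) == 2L) {
    a <- find(grp[1]); b <- find(grp[2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(kt, find, integer(1))
  length(unique(roots)) == 1L
}

#' Tight boundary of a 2D point cloud
#'
#' Concave ("alpha"-style) boundary via circumradius filtration of the
#' Delaunay triangulation, analogous to a shrink-factor boundary: triangles
#' are kept up to a circumradius threshold. With `alpha = 1` the threshold is
#' the smallest one for which every point is still covered and the kept
#' triangles form a single connected region (the tightest valid boundary);
#' `alpha = 0` keeps everything (the convex hull). Intermediate values
#' interpolate along the sorted circumradius spectrum.
#'
#' @param pts numeric matrix with columns x, y.
#' @param alpha shrink factor in `[0, 1]`.
#' @return list with `area` (µm²), `polygon` (two-column matrix tracing the
#'   outer boundary, closed implicitly), and `tri`/`keep` internals.
#' @export
tight_boundary <- function(pts, alpha = 1) {
  stopifnot(alpha >= 0, alpha <= 1)
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3L) return(list(area = 0, polygon = pts))
  d <- delaunay2d(pts)
  if (nrow(d$tri) == 0L) return(list(area = 0, polygon = pts))
  rad <- d$circumradius
  ord <- sort(unique(rad))
  covers <- function(keep) length(unique(as.vector(d$tri[keep, ]))) == n
  ok <- function(thr) {
    keep <- rad <= thr
    any(keep) && covers(keep) && .tris_connected(d$tri, keep)
  }
  # smallest valid threshold by binary search over the radius spectrum
  lo <- 1L; hi <- length(ord)
  if (!ok(ord[hi])) {
    # disconnected even at the convex hull level (should not happen)
    keep <- rep(TRUE, length(rad))
  } else {
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (ok(ord[mid])) hi <- mid else lo <- mid + 1L
    }
    i_crit <- hi
    i_use <- i_crit + as.integer(round((1 - alpha) * (length(ord) - i_crit)))
    keep <- rad <= ord[i_use]
  }
  area <- sum(d$area[keep])
  poly <- .boundary_polygon(d$tri[keep, , drop = FALSE], pts)
  list(area = area, polygon = poly, tri = d$tri, keep = keep)
}

# outer boundary polygon of a triangle complex (largest loop by |area|)
.boundary_polygon <- function(T, pts) {
  if (nrow(T) == 0L) return(NULL)
  e <- rbind(T[, c(1, 2), drop = FALSE], T[, c(2, 3), drop = FALSE],
             T[, c(3, 1), drop = FALSE])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- paste(a, b)
  cnt <- table(key)
  on_b <- key %in% names(cnt)[cnt == 1L]
  eb <- unique(cbind(a[on_b], b[on_b]))
  if (nrow(eb) < 3L) return(NULL)
  adj <- list()
  for (i in seq_len(nrow(eb))) {
    adj[[as.character(eb[i, 1])]] <- c(adj[[as.character(eb[i, 1])]], i)
    adj[[as.character(eb[i, 2])]] <- c(adj[[as.character(eb[i, 2])]], i)
  }
  used <- logical(nrow(eb))
  loops <- list()
  for (s in seq_len(nrow(eb))) {
    if (used[s]) next
    loop <- eb[s, 1]
    cur <- eb[s, 2]
    used[s] <- TRUE
    repeat {
      loop <- c(loop, cur)
      nxt <- adj[[as.character(cur)]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      i <- nxt[1]
      used[i] <- TRUE
      cur <- if (eb[i, 1] == cur) eb[i, 2] else eb[i, 1]
      if (cur == loop[1]) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  areas <- vapply(loops, function(l) abs(.shoelace(pts[l, , drop = FALSE])),
                  numeric(1))
  pts[loops[[which.max(areas)]], , drop = FALSE]
}

.shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Convex hull area of 2D points
#'
#' @param pts numeric matrix with columns x, y.
#' @return area in µm² (0 for degenerate inputs).
#' @export
convex_area <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) return(0)
  abs(.shoelace(pts[h, , drop = FALSE]))
}

#' Spanning area of a tree
#'
#' 2D area of the spanning field of the node coordinates (x, y; z ignored).
#' The default is the tight concave boundary with shrink factor
#' `alpha = 1`; `method = "convex"` uses the convex hull, which is what the
#' wire-optimality scaling pipeline uses. For very dense reconstructions the
#' node cloud is thinned to `max_points` nodes before triangulation; the
#' boundary is insensitive to interior thinning at the default resolution.
#'
#' @param t a [dtree].
#' @param method `"concave"` or `"convex"`.
#' @param alpha shrink factor for the concave boundary.
#' @param max_points thinning cap for the concave method.
#' @return area in µm².
#' @export
spanning_area <- function(t, method = c("concave", "convex"), alpha = 1,
                          max_points = 1500) {
  method <- match.arg(method)
  pts <- cbind(t$x, t$y)
  if (method == "convex") return(convex_area(pts))
  if (nrow(pts) > max_points)
    pts <- pts[seq(1, nrow(pts), length.out = max_points), , drop = FALSE]
  tight_boundary(pts, alpha = alpha)$area
}
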