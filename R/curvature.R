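#' Normalised bending-curvature increase of an oriented branch
#'
#' Geometric model of a tubular dendrite branch bending on the larval body
#' wall, approximated as the surface of a cylinder of radius R whose axis
#' of symmetry runs dorsoventrally. A branch of fixed length L_b oriented
#' at angle theta to the cylinder axis (theta = pi/2: along the
#' anteroposterior contraction direction, perpendicular to the axis;
#' theta = 0: along the axis, i.e. parallel to the main branch) follows an
#' elliptical profile with semi-diameters `a = L_b / (2*pi)` and
#' `b = a / sin(theta)`, approximated by a circular arc of radius
#' `Rc = (a + b) / 2`. For a thin tube (R >> tube radius) the second
#' principal curvature is essentially unchanged by bending, so the change
#' in the first principal curvature `c1 = 1/Rc` carries the mechanical
#' signal. Rescaling c1 by its maximal value at theta = pi/2 (where
#' Rc = a, a fully circular branch) gives the closed form
#'
#'   f(theta) = 2 * sin(theta) / (1 + sin(theta)),
#'
#' which runs from 0 for a straight branch (theta = 0) to 1 for a fully
#' bent branch (theta = pi/2), is strictly increasing, and is independent
#' of both the branch length and the cylinder size.
#'
#' @param theta orientation angle(s) in radians, within `[0, pi/2]`.
#' @return normalised curvature increase in `[0, 1]`.
#' @export
normalized_curvature_increase <- function(theta) {
  if (any(theta < -1e-12 | theta > pi / 2 + 1e-12, na.rm = TRUE))
    stop("theta must lie in [0, pi/2]; fold orientation angles first")
  theta <- pmin(pmax(theta, 0), pi / 2)
  2 * sin(theta) / (1 + sin(theta))
}

#' Per-branch normalised curvature increase
#'
#' Applies [normalized_curvature_increase()] to every segment orientation
#' angle of each branch record (angles in degrees, already folded to
#' `[0, 90]`), and aggregates within the branch. The primary aggregate is
#' the segment-length-weighted mean (invariant under resampling); the
#' unweighted mean and the median of segment values are also reported.
#'
#' @param branches a branch table from [branch_table()] (needs list columns
#'   `segment_angles` and `segment_lengths`).
#' @return the input data.frame with added columns `curvature` (length-
#'   weighted mean), `curvature_mean`, `curvature_median`; branches without
#'   any valid segment get `NA`.
#' @export
branch_curvature_increase <- function(branches) {
  vals <- lapply(branches$segment_angles,
                 function(a) normalized_curvature_increase(a * pi / 180))
  branches$curvature <- mapply(function(v, l) {
    ok <- !is.na(v) & l > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * l[ok]) / sum(l[ok])
  }, vals, branches$segment_lengths)
  branches$curvature_mean <- vapply(vals, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE), numeric(1))
  branches$curvature_median <- vapply(vals, function(v)
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE),
    numeric(1))
  branches
}
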