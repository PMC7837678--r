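#' Normalised segment-contraction rate from a soma triplet
#'
#' The body-wall contraction of a segment is tracked through three
#' adjacent cell somata along the anteroposterior axis. The raw signal is
#' the sum of the Euclidean distances from the central soma to the
#' anterior and posterior somata per frame; it is affinely normalised to
#' `[0, 1]` with 0 at maximal distension (largest distance sum) and 1 at
#' maximal contraction (smallest distance sum).
#'
#' @param traj list with numeric `times` (s) and two-column matrices
#'   `central`, `anterior`, `posterior` (positions in µm, one row per
#'   frame).
#' @return list with `times` and `contraction` (in `[0, 1]`).
#' @export
contraction_rate <- function(traj) {
  stopifnot(length(traj$times) >= 2)
  d <- sqrt(rowSums((traj$central - traj$anterior)^2)) +
       sqrt(rowSums((traj$central - traj$posterior)^2))
  if (max(d) == min(d))
    stop("constant soma distances: contraction normalisation undefined")
  list(times = traj$times, contraction = (max(d) - d) / (max(d) - min(d)))
}

#' Ratiometric fluorescence fold change
#'
#' Computes R = F_green / F_red per frame and the baseline-normalised
#' fold change dR/R0 = (R - R0) / R0 with R0 the mean of R over the
#' first five frames. Frames with zero red-channel intensity give
#' missing values.
#'
#' @param trace list (or data.frame) with `times` (s), `f_green` and
#'   `f_red` intensity vectors.
#' @return list with `times`, `ratio` and `drr0`.
#' @export
delta_r_over_r <- function(trace) {
  stopifnot(length(trace$times) >= 5)
  R <- ifelse(trace$f_red > 0, trace$f_green / trace$f_red, NA_real_)
  r0 <- mean(R[1:5])
  list(times = trace$times, ratio = R, drr0 = (R - r0) / r0)
}

#' Align trials to maximal contraction and average
#'
#' Shifts every trial so that its maximal segment contraction sits at
#' t = 0 s (ties resolved to the earliest frame), normalises each trial's
#' fold-change trace by its (positive) maximum, and averages across trials
#' on the shared frame grid. Mean and SEM are reported only at offsets
#' where at least `min_trials` trials contribute. The lag of the mean
#' fold-change peak relative to maximal contraction is returned.
#'
#' @param contractions list of outputs of [contraction_rate()].
#' @param drr0s list of outputs of [delta_r_over_r()] (same trials, same
#'   frame interval).
#' @param dt frame interval (s).
#' @param min_trials minimum number of contributing trials per offset.
#' @return list with `offset` (s), `mean_contraction`, `sem_contraction`,
#'   `mean_drr0`, `sem_drr0`, `n_trials` per offset, and `peak_lag` (s).
#' @export
align_and_average <- function(contractions, drr0s, dt = 0.2,
                              min_trials = 5) {
  stopifnot(length(contractions) == length(drr0s),
            length(contractions) >= 1)
  n_tr <- length(contractions)
  peak <- vapply(contractions, function(ct) which.max(ct$contraction),
                 integer(1))   # which.max: earliest frame on ties
  offsets <- lapply(seq_len(n_tr), function(i)
    seq_along(contractions[[i]]$contraction) - peak[i])
  rng <- range(unlist(offsets))
  grid <- rng[1]:rng[2]
  acc_c <- acc_d <- matrix(NA_real_, n_tr, length(grid))
  for (i in seq_len(n_tr)) {
    idx <- match(offsets[[i]], grid)
    acc_c[i, idx] <- contractions[[i]]$contraction
    d <- drr0s[[i]]$drr0
    dmax <- max(d, na.rm = TRUE)
    if (is.finite(dmax) && dmax > 0) d <- d / dmax
    acc_d[i, idx] <- d
  }
  n_per <- colSums(!is.na(acc_c))
  ok <- n_per >= min_trials
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sem_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  mc <- apply(acc_c, 2, mean_na); mc[!ok] <- NA_real_
  md <- apply(acc_d, 2, mean_na); md[!ok] <- NA_real_
  sc <- apply(acc_c, 2, sem_na); sc[!ok] <- NA_real_
  sd_ <- apply(acc_d, 2, sem_na); sd_[!ok] <- NA_real_
  peak_lag <- if (all(is.na(md))) NA_real_ else
    grid[which.max(md)] * dt
  list(offset = grid * dt, mean_contraction = mc, sem_contraction = sc,
       mean_drr0 = md, sem_drr0 = sd_, n_trials = n_per,
       peak_lag = peak_lag)
}
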