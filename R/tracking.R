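#' Match terminal branches between two time-lapse frames
#'
#' Terminal branches are identified by their termination points, whose
#' correspondence across frames comes from a registration table (manual
#' registration of real data or exact ground truth for synthetic series).
#' Every track id may label at most one termination point per frame.
#'
#' @param t0,t1 [dtree]s of the two frames.
#' @param reg0,reg1 registration data.frames for each frame, with columns
#'   `node_id` (node index of a termination point in that frame's tree) and
#'   `track_id`.
#' @return data.frame of branch pairs: `track_id`, `tip0`, `tip1`,
#'   `length0`, `length1` (NA where the branch is absent in a frame:
#'   absent at t0 = candidate new branch, absent at t1 = retracted).
#' @export
match_branches <- function(t0, t1, reg0, reg1) {
  for (reg in list(reg0, reg1)) {
    dup <- reg$track_id[duplicated(reg$track_id)]
    if (length(dup) > 0L)
      stop("one-to-many registration for track id(s): ",
           paste(unique(dup), collapse = ", "))
  }
  tb0 <- dissect_terminal_branches(t0)
  tb1 <- dissect_terminal_branches(t1)
  tr0 <- reg0$track_id[match(tb0$tip, reg0$node_id)]
  tr1 <- reg1$track_id[match(tb1$tip, reg1$node_id)]
  if (anyNA(tr0) || anyNA(tr1))
    stop("registration missing for some termination points")
  all_tracks <- union(tr0, tr1)
  i0 <- match(all_tracks, tr0)
  i1 <- match(all_tracks, tr1)
  data.frame(track_id = all_tracks,
             tip0 = tb0$tip[i0], tip1 = tb1$tip[i1],
             length0 = tb0$length[i0], length1 = tb1$length[i1])
}

#' Classify branch dynamics between two frames
#'
#' Partitions matched terminal branches into the five dynamics classes:
#' `new` (absent at t0), `retracted` (absent at t1), and among branches
#' present in both frames `elongated` / `shortened` when the length change
#' exceeds the optical resolution threshold, `stable` otherwise.
#'
#' @param pairs branch pairs from [match_branches()].
#' @param t0,t1 frame times (hours AEL), `t1 > t0`.
#' @param resolution length-change threshold (µm) below which a branch is
#'   considered stable (default 0.3, approximately the lateral optical
#'   resolution of confocal imaging).
#' @return data.frame of branch events: `track_id`, `t0`, `t1`, `class`,
#'   `delta_length` (µm; full length for new, minus full length for
#'   retracted) and `rate` (µm/hr).
#' @export
classify_dynamics <- function(pairs, t0, t1, resolution = 0.3) {
  if (t1 <= t0) stop("t1 must be later than t0")
  dt <- t1 - t0
  delta <- ifelse(is.na(pairs$length0), pairs$length1,
                  ifelse(is.na(pairs$length1), -pairs$length0,
                         pairs$length1 - pairs$length0))
  cls <- ifelse(is.na(pairs$length0), "new",
                ifelse(is.na(pairs$length1), "retracted",
                       ifelse(delta > resolution, "elongated",
                              ifelse(delta < -resolution, "shortened",
                                     "stable"))))
  data.frame(track_id = pairs$track_id, t0 = t0, t1 = t1, class = cls,
             delta_length = delta, rate = delta / dt)
}

#' Track a whole time series
#'
#' Convenience wrapper applying [match_branches()] and
#' [classify_dynamics()] to every consecutive frame pair of a series.
#'
#' @param series list with `trees` (list of [dtree]), `times` (hours AEL)
#'   and `registration` (data.frame with columns `frame`, `node_id`,
#'   `track_id`).
#' @param resolution see [classify_dynamics()].
#' @return data.frame of branch events over all frame pairs.
#' @export
track_series <- function(series, resolution = 0.3) {
  reg <- split(series$registration, series$registration$frame)
  out <- list()
  for (i in seq_len(length(series$trees) - 1L)) {
    pairs <- match_branches(series$trees[[i]], series$trees[[i + 1L]],
                            reg[[as.character(i)]],
                            reg[[as.character(i + 1L)]])
    out[[i]] <- classify_dynamics(pairs, series$times[i],
                                  series$times[i + 1L],
                                  resolution = resolution)
  }
  do.call(rbind, out)
}

#' Per-bin dynamics summary
#'
#' Bins branch events by the time of the later frame into right-closed
#' 1-hour bins (default edges 17.5-21.5 h AEL) and reports the fraction of
#' each dynamics class (summing to 1 over classified branches per bin) and
#' the mean absolute extension (new + elongated) and reduction
#' (retracted + shortened) rates.
#'
#' @param events branch events from [classify_dynamics()]/[track_series()].
#' @param bin_edges right edges of the time bins (hours AEL).
#' @return data.frame with one row per non-empty bin: `bin_end`, `n`,
#'   `frac_new`, `frac_retracted`, `frac_shortened`, `frac_elongated`,
#'   `frac_stable`, `mean_extension_rate`, `mean_reduction_rate`,
#'   `mean_retracted_length`, `mean_new_length`.
#' @export
dynamics_summary <- function(events,
                             bin_edges = c(17.5, 18.5, 19.5, 20.5, 21.5)) {
  bin <- bin_edges[findInterval(events$t1, bin_edges, left.open = TRUE,
                                rightmost.closed = FALSE) + 1L]
  keep <- !is.na(bin)
  events <- events[keep, , drop = FALSE]
  bin <- bin[keep]
  rows <- lapply(sort(unique(bin)), function(b) {
    e <- events[bin == b, , drop = FALSE]
    n <- nrow(e)
    frac <- function(cl) sum(e$class == cl) / n
    ext <- abs(e$rate[e$class %in% c("new", "elongated")])
    red <- abs(e$rate[e$class %in% c("retracted", "shortened")])
    data.frame(
      bin_end = b, n = n,
      frac_new = frac("new"), frac_retracted = frac("retracted"),
      frac_shortened = frac("shortened"),
      frac_elongated = frac("elongated"), frac_stable = frac("stable"),
      mean_extension_rate = if (length(ext)) mean(ext) else NA_real_,
      mean_reduction_rate = if (length(red)) mean(red) else NA_real_,
      mean_retracted_length = {
        r <- abs(e$delta_length[e$class == "retracted"])
        if (length(r)) mean(r) else NA_real_
      },
      mean_new_length = {
        r <- e$delta_length[e$class == "new"]
        if (length(r)) mean(r) else NA_real_
      })
  })
  do.call(rbind, rows)
}
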