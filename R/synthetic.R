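# Seeded generators for every input the analysis chain consumes, each with
# exact ground truth so the estimators have parameter-recovery tests.

#' Parameters of the synthetic comb-dendrite generator
#'
#' Defaults emulate the comb-like morphology of class I vpda dendrites at
#' the peak of branching complexity: one long vertical main branch, long
#' second-order lateral branches oriented towards the anteroposterior
#' (horizontal) axis with a peaked angle distribution, and short
#' higher-order branches with a flat orientation-angle distribution
#' (medians near 6 µm / ~63 deg for second-order and ~1.8 µm / ~45 deg for
#' higher-order branches).
#'
#' @param mb_length main-branch length (µm).
#' @param n_laterals number of second-order lateral branches (two of them
#'   attach at the main-branch tip, forming the top of the comb).
#' @param so_length_median,so_length_sdlog lognormal length parameters of
#'   second-order branches (µm).
#' @param so_angle_mean,so_angle_sd normal orientation-angle parameters of
#'   second-order branches (degrees, truncated to `[30, 88]`).
#' @param ho_rate mean number (Poisson) of higher-order branches per
#'   second-order branch.
#' @param ho_length_median,ho_length_sdlog lognormal length parameters of
#'   higher-order branches (µm).
#' @param ho_angle_range uniform orientation-angle range of higher-order
#'   branches (degrees; flat distribution).
#' @param seg_angle_jitter per-segment angular jitter sd (degrees).
#' @param jitter positional noise sd applied to non-root nodes (µm).
#' @param spacing node spacing of the generated cable (µm).
#' @return list of class `comb_params`.
#' @export
comb_params <- function(mb_length = 50, n_laterals = 16,
                        so_length_median = 6, so_length_sdlog = 0.35,
                        so_angle_mean = 63, so_angle_sd = 10,
                        ho_rate = 1.5,
                        ho_length_median = 1.8, ho_length_sdlog = 0.3,
                        ho_angle_range = c(5, 85),
                        seg_angle_jitter = 5,
                        jitter = 0.05,
                        spacing = 0.5) {
  stopifnot(mb_length > 0, n_laterals >= 2, so_length_median > 0,
            ho_length_median > 0, spacing > 0,
            all(ho_angle_range >= 0 & ho_angle_range <= 90))
  structure(as.list(environment()), class = "comb_params")
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic comb dendrite with ground truth
#'
#' Builds a comb tree per [comb_params()]: a vertical main branch rooted at
#' the origin, lateral branches with known per-segment orientation angles
#' (slightly downward-pointing so the main-branch tip caps the bounding
#' box), and higher-order branches constrained to be shorter than their
#' parent's remaining cable so that the planted branch length order is the
#' one the ordering analysis must recover.
#'
#' @param p a [comb_params()].
#' @param seed integer seed.
#' @return list with `tree` (a [dtree]), `branches` (ground-truth table:
#'   `order_class`, `blo`, `length`, `mean_angle`, `attach_id`, `tip_id`),
#'   `mb_tip_id`, `params`, `seed`.
#' @export
make_comb_tree <- function(p = comb_params(), seed = 1) {
  set.seed(seed)
  sp <- p$spacing
  # main branch
  ys <- seq(0, p$mb_length, by = sp)
  if (ys[length(ys)] < p$mb_length) ys <- c(ys, p$mb_length)
  X <- numeric(length(ys)); Y <- ys; PAR <- c(0L, seq_len(length(ys) - 1L))
  mb_tip <- length(ys)
  n_inner <- p$n_laterals - 2L
  inner_h <- sort(stats::runif(n_inner, 2, p$mb_length - 2))
  attach_mb <- vapply(inner_h, function(h) which.min(abs(Y[1:mb_tip] - h)),
                      integer(1))
  attach_mb <- c(attach_mb, mb_tip, mb_tip)   # top pair at the MB tip
  sides <- rep_len(c(-1, 1), n_inner)
  sides <- c(sides[sample.int(n_inner)], -1, 1)

  gt <- list()
  # grow one polyline branch; returns updated store and node bookkeeping
  add_branch <- function(attach, side, theta_deg, len, steep_top = FALSE) {
    n_seg <- max(2L, round(len / 2))
    seg_len <- rep(len / n_seg, n_seg)
    th <- .rtrunc_norm(n_seg, theta_deg, p$seg_angle_jitter, 1, 89)
    if (steep_top) th <- .rtrunc_norm(n_seg, theta_deg, 2, 60, 89)
    nodes_of_branch <- integer(0)
    cur <- attach
    for (s in seq_len(n_seg)) {
      rad <- th[s] * pi / 180
      dir <- c(side * sin(rad), -cos(rad))
      n_sub <- max(1L, ceiling(seg_len[s] / sp))
      step <- seg_len[s] / n_sub
      for (u in seq_len(n_sub)) {
        X <<- c(X, X[cur] + dir[1] * step)
        Y <<- c(Y, Y[cur] + dir[2] * step)
        PAR <<- c(PAR, cur)
        cur <- length(X)
        nodes_of_branch <- c(nodes_of_branch, cur)
      }
    }
    list(nodes = nodes_of_branch, tip = cur,
         mean_angle = mean(th), length = len)
  }

  so_len <- stats::rlnorm(p$n_laterals, log(p$so_length_median),
                          p$so_length_sdlog)
  so_ang <- .rtrunc_norm(p$n_laterals, p$so_angle_mean, p$so_angle_sd, 30, 88)
  bid <- 0L
  gt_nodes <- list()
  for (i in seq_len(p$n_laterals)) {
    top <- i > n_inner
    b <- add_branch(attach_mb[i], sides[i], so_ang[i],
                    if (top) max(so_len[i], 4) else so_len[i],
                    steep_top = top)
    bid <- bid + 1L
    gt[[bid]] <- data.frame(branch_id = bid, order_class = "second_order",
                            blo = 1L, length = b$length,
                            mean_angle = b$mean_angle,
                            attach_id = attach_mb[i], tip_id = b$tip,
                            parent_branch = NA_integer_)
    gt_nodes[[bid]] <- b$nodes
    if (top) next   # keep the comb top clean so the MB stays recoverable
    # higher-order branches off this lateral, in pairs sharing an
    # attachment node (spiky clusters; removing one member later leaves
    # the attachment a branch point, so no terminal branch is disturbed)
    n_pairs <- stats::rpois(1, p$ho_rate / 2)
    if (n_pairs == 0L) next
    nodes <- b$nodes
    cum <- seq_along(nodes) * (b$length / length(nodes))
    for (pair in seq_len(n_pairs)) {
      cand <- which(b$length - cum > 1.2)       # enough remaining cable
      cand <- cand[cand > 1 & cand < length(nodes)]
      if (length(cand) == 0L) break
      at <- nodes[if (length(cand) == 1L) cand else sample(cand, 1)]
      remaining <- b$length - cum[match(at, nodes)]
      for (m in 1:2) {
        hl <- min(stats::rlnorm(1, log(p$ho_length_median),
                                p$ho_length_sdlog),
                  0.7 * remaining)
        if (hl < 0.4) next
        ha <- stats::runif(1, p$ho_angle_range[1], p$ho_angle_range[2])
        hb <- add_branch(at, sample(c(-1, 1), 1), ha, hl)
        bid <- bid + 1L
        gt[[bid]] <- data.frame(branch_id = bid,
                                order_class = "higher_order",
                                blo = 2L, length = hb$length,
                                mean_angle = hb$mean_angle,
                                attach_id = at, tip_id = hb$tip,
                                parent_branch = i)
        gt_nodes[[bid]] <- hb$nodes
      }
    }
  }
  if (p$jitter > 0) {
    nn <- length(X)
    X[-1] <- X[-1] + stats::rnorm(nn - 1L, 0, p$jitter)
    Y[-1] <- Y[-1] + stats::rnorm(nn - 1L, 0, p$jitter)
  }
  tree <- dtree(x = X, y = Y, z = 0, r = 0.15, parent = PAR)
  branches <- do.call(rbind, gt)
  if (p$jitter > 0) {
    # recompute realised per-branch mean angles from the jittered geometry
    branches$mean_angle <- vapply(seq_along(gt_nodes), function(i) {
      nd <- gt_nodes[[i]]
      dx <- X[nd] - X[PAR[nd]]
      dy <- Y[nd] - Y[PAR[nd]]
      mean(atan2(abs(dx), abs(dy)) * 180 / pi)
    }, numeric(1))
    branches$length <- vapply(seq_along(gt_nodes), function(i) {
      nd <- gt_nodes[[i]]
      sum(sqrt((X[nd] - X[PAR[nd]])^2 + (Y[nd] - Y[PAR[nd]])^2))
    }, numeric(1))
  }
  list(tree = tree, branches = branches, mb_tip_id = mb_tip,
       params = p, seed = seed)
}

#' Parameters of the synthetic time-lapse generator
#'
#' Per-transition (1-hour) event fractions and rates, emulating the
#' embryonic developmental trajectory: an extension-dominated start (many
#' newly formed branches), a retraction phase around 18.5-19.5 h AEL in
#' which nearly half of the branches reduce while new branches become
#' rare, and stabilisation towards 21.5 h, with extension and reduction
#' rates centred between 2 and 3 µm/hr throughout.
#'
#' Branches selected for reduction lose cable at the drawn rate; whether
#' that realises as a shortened or a fully retracted branch depends on
#' the branch's own length, exactly as in the biological interpretation:
#' a constant random reduction penalises short branches, which are the
#' ones that can disappear entirely within one frame interval.
#'
#' @param times frame times (hours AEL; transitions happen between
#'   consecutive frames).
#' @param frac_reduced per-transition fraction of branches whose tips are
#'   reduced (realised as shortened or retracted depending on length).
#' @param frac_new,frac_elongated per-transition class fractions
#'   (remainder is stable).
#' @param rate_mean,rate_sd reduction/elongation rate distribution
#'   (µm/hr).
#' @param new_len_mean_pre,new_len_mean_post,new_len_sd length of newly
#'   formed branches before/after 19.5 h AEL (µm).
#' @param resolution analysis resolution floor (µm); planted non-stable
#'   length changes are kept above twice this value.
#' @return list of class `timelapse_params`.
#' @export
timelapse_params <- function(times = seq(16.5, 21.5, by = 1),
                             frac_reduced   = c(0.25, 0.38, 0.50, 0.30, 0.18),
                             frac_new       = c(0.45, 0.35, 0.20, 0.06, 0.02),
                             frac_elongated = c(0.27, 0.25, 0.15, 0.15, 0.18),
                             rate_mean = 2.5, rate_sd = 0.5,
                             new_len_mean_pre = 2.5,
                             new_len_mean_post = 1.81,
                             new_len_sd = 0.3,
                             resolution = 0.3) {
  nb <- length(times) - 1L
  for (f in list(frac_reduced, frac_new, frac_elongated))
    stopifnot(length(f) == nb, all(f >= 0 & f <= 1))
  stopifnot(all(frac_reduced + frac_elongated <= 1))
  structure(as.list(environment()), class = "timelapse_params")
}

# --- id-addressed tree edits used by the time-lapse generator ------------

.append_branch <- function(t, attach_idx, angle_deg, side, len,
                           spacing = 0.5, id0 = max(t$id)) {
  rad <- angle_deg * pi / 180
  dir <- c(side * sin(rad), -cos(rad))
  n_sub <- max(1L, ceiling(len / spacing))
  step <- len / n_sub
  n0 <- n_nodes(t)
  for (u in seq_len(n_sub)) {
    t$x <- c(t$x, t$x[attach_idx] + dir[1] * step * u)
    t$y <- c(t$y, t$y[attach_idx] + dir[2] * step * u)
    t$z <- c(t$z, t$z[attach_idx])
    t$r <- c(t$r, t$r[attach_idx])
    t$type <- c(t$type, t$type[attach_idx])
    t$id <- c(t$id, id0 + u)
    t$parent <- c(t$parent, if (u == 1L) attach_idx else n0 + u - 1L)
  }
  list(tree = t, tip_id = id0 + n_sub)
}

.extend_tip <- function(t, tip_idx, len, spacing = 0.5, id0 = max(t$id)) {
  p <- t$parent[tip_idx]
  d <- c(t$x[tip_idx] - t$x[p], t$y[tip_idx] - t$y[p])
  nd <- sqrt(sum(d^2))
  dir <- if (nd > 0) d / nd else c(1, 0)
  n_sub <- max(1L, ceiling(len / spacing))
  step <- len / n_sub
  n0 <- n_nodes(t)
  for (u in seq_len(n_sub)) {
    t$x <- c(t$x, t$x[tip_idx] + dir[1] * step * u)
    t$y <- c(t$y, t$y[tip_idx] + dir[2] * step * u)
    t$z <- c(t$z, t$z[tip_idx]); t$r <- c(t$r, t$r[tip_idx])
    t$type <- c(t$type, t$type[tip_idx])
    t$id <- c(t$id, id0 + u)
    t$parent <- c(t$parent, if (u == 1L) tip_idx else n0 + u - 1L)
  }
  list(tree = t, tip_id = id0 + n_sub)
}

# is removing this terminal branch free of side effects on other branches?
.safe_retract <- function(t, tb_row, kids) {
  a <- tb_row$start
  ch <- kids[[a]]
  if (length(ch) != 2L) return(length(ch) > 2L)
  other <- setdiff(ch, tb_row$node_path[[1]][2])
  # walk downstream from the sibling: safe unless we hit a tip before a bp
  v <- other
  repeat {
    cv <- kids[[v]]
    if (is.null(cv) || length(cv) == 0L) return(FALSE)
    if (length(cv) >= 2L) return(TRUE)
    v <- cv[1]
  }
}

#' Generate a synthetic time-lapse series with planted branch events
#'
#' Starting from a base tree (typically a [make_comb_tree()] output),
#' applies per-transition planted events: retraction (branch removed),
#' shortening, elongation and newly formed branches, at the configured
#' class fractions and rates, with the remainder stable. Events are
#' planted only where they do not alter the measured length of any other
#' terminal branch (a branch whose removal would merge cable into another
#' terminal branch, or an attachment point inside another terminal
#' branch's path, is not selected), so the planted event table is the
#' exact ground truth for the tracking analysis. Exact point
#' correspondences are recorded as a registration table.
#'
#' @param p a [timelapse_params()].
#' @param base a [dtree]; its main-branch tip terminal (if any) is kept
#'   stable.
#' @param seed integer seed.
#' @return list with `trees`, `times`, `registration` (frame, node_id,
#'   track_id), and `events` (ground truth: track_id, t0, t1, class,
#'   delta_length, rate).
#' @export
make_timelapse <- function(p = timelapse_params(), base, seed = 1) {
  set.seed(seed)
  trees <- list(base)
  times <- p$times
  n_tr <- length(times) - 1L
  # track bookkeeping by persistent node id
  tip_ids <- base$id[is_terminal(base)]
  track_of <- stats::setNames(as.list(seq_along(tip_ids)),
                              as.character(tip_ids))
  next_track <- length(tip_ids) + 1L
  reg <- list(data.frame(frame = 1L,
                         node_id = match(as.integer(names(track_of)), base$id),
                         track_id = unname(unlist(track_of))))
  events <- list()
  cur <- base
  max_id <- max(base$id)   # ids are never reused, even after removals
  for (tr in seq_len(n_tr)) {
    t0 <- times[tr]; t1 <- times[tr + 1L]
    tb <- dissect_terminal_branches(cur)
    kids <- children_list(cur)
    n_term <- nrow(tb)
    n_red <- round(p$frac_reduced[tr] * n_term)
    n_new <- round(p$frac_new[tr] * n_term)
    n_elo <- round(p$frac_elongated[tr] * n_term)
    safe <- vapply(seq_len(n_term), function(i)
      .safe_retract(cur, tb[i, ], kids), logical(1))
    rate_draw <- function(n) pmax(abs(stats::rnorm(n, p$rate_mean,
                                                   p$rate_sd)),
                                  2.5 * p$resolution)
    # reduction: drawn amount decides shortened vs retracted; a branch that
    # would vanish but whose removal would cascade into another terminal
    # branch's measurement is left untouched this frame
    red_rows <- if (n_red > 0) sample(n_term, min(n_red, n_term))
                else integer(0)
    red_amt <- rate_draw(length(red_rows)) * (t1 - t0)
    vanish <- red_amt >= tb$length[red_rows] - 1.5 * p$resolution
    ret_cand <- red_rows[vanish & safe[red_rows]]
    sho_rows <- red_rows[!vanish]
    sho_amt <- red_amt[!vanish]
    rest <- setdiff(seq_len(n_term), red_rows)
    elo_rows <- if (n_elo > 0 && length(rest))
      sample(rest, min(n_elo, length(rest))) else integer(0)

    # terminal-path nodes (off-limits for new attachments), by index
    term_nodes <- unique(unlist(lapply(tb$node_path, function(q) q[-1])))
    ev <- list()
    # (1) retract: apply sequentially, re-checking safety on the evolving
    # tree so joint removals can neither orphan a branch point nor merge
    # cable into a surviving terminal branch
    nxt <- cur
    ret_rows <- integer(0)
    for (i in ret_cand) {
      tid_i <- cur$id[tb$tip[i]]
      tbn <- dissect_terminal_branches(nxt)
      row <- match(match(tid_i, nxt$id), tbn$tip)
      if (is.na(row)) next
      if (!.safe_retract(nxt, tbn[row, ], children_list(nxt))) next
      nxt <- drop_nodes(nxt, tbn$node_path[[row]][-1])
      ret_rows <- c(ret_rows, i)
      tid <- as.character(tid_i)
      ev[[length(ev) + 1L]] <- data.frame(
        track_id = track_of[[tid]], t0 = t0, t1 = t1, class = "retracted",
        delta_length = -tb$length[i], rate = -tb$length[i] / (t1 - t0))
      track_of[[tid]] <- NULL
    }
    # (2) shorten (by id addressing on the updated tree)
    for (k in seq_along(sho_rows)) {
      i <- sho_rows[k]
      amt <- sho_amt[k]
      tid <- as.character(cur$id[tb$tip[i]])
      path_ids <- cur$id[tb$node_path[[i]]]
      tip_idx <- match(as.integer(tid), nxt$id)
      nxt <- shorten_terminal(nxt, tip_idx, amt)
      surv <- path_ids[path_ids %in% nxt$id]
      new_tip_id <- as.character(surv[length(surv)])
      if (new_tip_id != tid) {
        track_of[[new_tip_id]] <- track_of[[tid]]
        track_of[[tid]] <- NULL
      }
      ev[[length(ev) + 1L]] <- data.frame(
        track_id = track_of[[new_tip_id]], t0 = t0, t1 = t1,
        class = "shortened", delta_length = -amt, rate = -amt / (t1 - t0))
    }
    # (3) elongate
    for (i in elo_rows) {
      amt <- rate_draw(1) * (t1 - t0)
      tid <- as.character(cur$id[tb$tip[i]])
      res <- .extend_tip(nxt, match(as.integer(tid), nxt$id), amt,
                         id0 = max_id)
      max_id <- res$tip_id
      nxt <- res$tree
      track_of[[as.character(res$tip_id)]] <- track_of[[tid]]
      track_of[[tid]] <- NULL
      ev[[length(ev) + 1L]] <- data.frame(
        track_id = track_of[[as.character(res$tip_id)]], t0 = t0, t1 = t1,
        class = "elongated", delta_length = amt, rate = amt / (t1 - t0))
    }
    # (4) new branches at safe continuation nodes
    if (n_new > 0) {
      mean_len <- if (t1 <= 19.5 + 1e-9) p$new_len_mean_pre
                  else p$new_len_mean_post
      for (j in seq_len(n_new)) {
        cand_ids <- cur$id[setdiff(which(is_continuation(cur)), term_nodes)]
        cand_ids <- cand_ids[cand_ids %in% nxt$id]
        if (length(cand_ids) == 0L) break
        aid <- if (length(cand_ids) == 1L) cand_ids else sample(cand_ids, 1)
        len <- max(stats::rnorm(1, mean_len, p$new_len_sd),
                   2.5 * p$resolution)
        res <- .append_branch(nxt, match(aid, nxt$id),
                              stats::runif(1, 20, 85),
                              sample(c(-1, 1), 1), len, id0 = max_id)
        max_id <- res$tip_id
        nxt <- res$tree
        track_of[[as.character(res$tip_id)]] <- next_track
        ev[[length(ev) + 1L]] <- data.frame(
          track_id = next_track, t0 = t0, t1 = t1, class = "new",
          delta_length = len, rate = len / (t1 - t0))
        next_track <- next_track + 1L
        term_nodes <- c(term_nodes, match(aid, cur$id))  # one branch per spot
      }
    }
    # (5) everything else is stable
    done <- vapply(ev, function(e) e$track_id, numeric(1))
    for (i in setdiff(seq_len(n_term), c(ret_rows, sho_rows, elo_rows))) {
      tid <- as.character(cur$id[tb$tip[i]])
      if (is.null(track_of[[tid]]) || track_of[[tid]] %in% done) next
      ev[[length(ev) + 1L]] <- data.frame(
        track_id = track_of[[tid]], t0 = t0, t1 = t1, class = "stable",
        delta_length = 0, rate = 0)
    }
    events[[tr]] <- do.call(rbind, ev)
    cur <- nxt
    trees[[tr + 1L]] <- cur
    live <- as.integer(names(track_of))
    reg[[tr + 1L]] <- data.frame(frame = tr + 1L,
                                 node_id = match(live, cur$id),
                                 track_id = unname(unlist(track_of)))
  }
  list(trees = trees, times = times,
       registration = do.call(rbind, reg),
       events = do.call(rbind, events),
       params = p, seed = seed)
}

#' Build a growth arena from a reference morphology
#'
#' Extracts the main branch of the reference tree and the tight contour
#' (shrink factor `alpha`) of its spanning field, the two ingredients of a
#' [growth_arena()].
#'
#' @param t a [dtree] (e.g. a synthetic comb at peak complexity).
#' @param alpha contour shrink factor (see [tight_boundary()]).
#' @return a [growth_arena].
#' @export
make_arena <- function(t, alpha = 1) {
  at <- find_main_branch(t)
  mbp <- at$mb_node_path
  mb <- dtree(x = at$tree$x[mbp], y = at$tree$y[mbp],
              z = at$tree$z[mbp], r = at$tree$r[mbp],
              parent = c(0L, seq_len(length(mbp) - 1L)))
  tb <- tight_boundary(cbind(at$tree$x, at$tree$y), alpha = alpha)
  if (is.null(tb$polygon)) stop("degenerate reference tree: no contour")
  growth_arena(mb, tb$polygon)
}

#' Parameters of the synthetic peristalsis generator
#'
#' @param n_trials number of crawling trials.
#' @param n_frames frames per trial.
#' @param dt frame interval (s).
#' @param baseline_dist resting soma spacing sum (µm).
#' @param depth relative contraction depth in `(0, 1)`.
#' @param lag_frames planted lag of the fluorescence peak after maximal
#'   contraction (frames).
#' @param r planted Pearson correlation between the contraction rate and
#'   the fold-change trace.
#' @param pos_noise positional noise sd of the soma tracks (µm).
#' @param amp fold-change amplitude at full contraction.
#' @return list of class `peristalsis_params`.
#' @export
peristalsis_params <- function(n_trials = 25, n_frames = 41, dt = 0.2,
                               baseline_dist = 60, depth = 0.3,
                               lag_frames = 1, r = 0.85,
                               pos_noise = 0.1, amp = 1.5) {
  stopifnot(n_frames >= 10, depth > 0, depth < 1, r > 0, r <= 1)
  structure(as.list(environment()), class = "peristalsis_params")
}

#' Generate soma-triplet trajectories with coupled fluorescence
#'
#' Each trial is one contraction-distension cycle: the summed distance of
#' a soma triplet follows a Gaussian contraction pulse, and the
#' green/red fluorescence ratio follows the contraction with a planted
#' frame lag, mixed with Gaussian noise calibrated to a planted Pearson
#' correlation.
#'
#' @param p a [peristalsis_params()].
#' @param seed integer seed.
#' @return list with `trajectories` (inputs for [contraction_rate()]),
#'   `traces` (inputs for [delta_r_over_r()]) and ground truth
#'   (`lag_s`, `r`, `peak_frame` per trial).
#' @export
make_peristalsis <- function(p = peristalsis_params(), seed = 1) {
  set.seed(seed)
  trajs <- traces <- vector("list", p$n_trials)
  peak_frame <- integer(p$n_trials)
  tt <- (seq_len(p$n_frames) - 1L) * p$dt
  for (i in seq_len(p$n_trials)) {
    centre <- sample(15:(p$n_frames - 15), 1)
    peak_frame[i] <- centre
    width <- stats::runif(1, 0.8, 1.4)   # FWHM, seconds
    c_t <- exp(-((tt - tt[centre])^2) / (2 * (width / 2.355)^2))
    d <- p$baseline_dist * (1 - p$depth * c_t)
    half <- d / 2
    trajs[[i]] <- list(
      times = tt,
      central = cbind(stats::rnorm(p$n_frames, 0, p$pos_noise),
                      stats::rnorm(p$n_frames, 0, p$pos_noise)),
      anterior = cbind(-half + stats::rnorm(p$n_frames, 0, p$pos_noise),
                       stats::rnorm(p$n_frames, 0, p$pos_noise)),
      posterior = cbind(half + stats::rnorm(p$n_frames, 0, p$pos_noise),
                        stats::rnorm(p$n_frames, 0, p$pos_noise)))
    # fluorescence: lagged contraction + noise at the planted correlation
    sig <- c(rep(0, p$lag_frames), c_t)[seq_len(p$n_frames)]
    z <- (sig - mean(sig)) / stats::sd(sig)
    noise_sd <- sqrt(1 / p$r^2 - 1)
    y <- z + stats::rnorm(p$n_frames, 0, noise_sd)
    R <- 1 + p$amp * stats::sd(sig) * y
    f_red <- rep(100, p$n_frames)
    traces[[i]] <- list(times = tt, f_green = R * f_red, f_red = f_red)
  }
  list(trajectories = trajs, traces = traces,
       lag_s = p$lag_frames * p$dt, r = p$r, peak_frame = peak_frame,
       params = p, seed = seed)
}
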