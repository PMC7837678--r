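#' Run the full analysis chain on synthetic data
#'
#' Deterministic end-to-end demonstration of the package: generates the
#' synthetic fixtures, computes morphometrics, runs the MST scaling
#' ensemble, the curvature analysis, the four retraction schemes, the
#' single-branch tracking summary, parameter extraction and a small
#' growth-model ensemble, and writes all result tables as CSV into
#' `out_dir` together with a manifest recording seeds and parameters.
#' Two runs with the same seed produce identical outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed; each stage derives its own sub-seed.
#' @param n_sims MST simulations for the scaling stage.
#' @param n_growth growth-model runs.
#' @param n_probe probe points per growth iteration (the full-scale model
#'   default of 100,000 can be lowered for quick runs; the manifest
#'   records the value used).
#' @return (invisibly) a named list of the main result tables.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_sims = 20, n_growth = 5,
                         n_probe = 5000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    x
  }
  # fixtures
  comb <- make_comb_tree(comb_params(), seed = seed)
  write_swc(comb$tree, file.path(out_dir, "comb.swc"))
  tl <- make_timelapse(timelapse_params(), base = comb$tree,
                       seed = seed + 1L)
  # morphometrics of the time-lapse frames
  morpho <- wr(cbind(time = tl$times, morphometric_table(tl$trees)),
               "morphometrics")
  # branch table + curvature of the peak-complexity frame
  peak <- which.max(vapply(tl$trees, function(t) sum(is_branch_point(t)),
                           integer(1)))
  at <- find_main_branch(tl$trees[[peak]])
  br <- branch_curvature_increase(branch_table(at))
  wr(br[, c("branch_id", "subtree_id", "blo", "order_class", "length",
            "mean_angle", "curvature", "curvature_mean",
            "curvature_median")], "branches")
  # scaling ensemble
  ens <- mst_scaling_ensemble(n_sims = n_sims, seed = seed + 2L)
  fit <- fit_scaling(ens)
  wr(data.frame(slope = fit$slope, intercept = fit$intercept,
                r_squared = fit$r_squared, n = fit$n), "scaling_fit")
  # retraction schemes against the real post-retraction frame
  N <- vapply(tl$trees, function(t) sum(is_branch_point(t)), integer(1))
  n_remove <- plan_removal_count(N)
  pre <- tl$trees[[which.max(N)]]
  post <- tl$trees[[which.max(N) - 1L + which.min(N[which.max(N):length(N)])]]
  sims <- list(
    shortest_first = apply_retraction_scheme(pre, "shortest_first", n_remove),
    low_angle_first = apply_retraction_scheme(pre, "low_angle_first",
                                              n_remove),
    high_blo_first = apply_retraction_scheme(pre, "high_blo_first", n_remove),
    random = apply_retraction_scheme(pre, "random", n_remove, n_reps = 20,
                                     seed = seed + 3L))
  schemes <- wr(compare_schemes(sims, post, seed = seed + 4L), "schemes")
  # tracking + growth parameters
  events <- track_series(tl)
  summ <- wr(dynamics_summary(events), "dynamics")
  gp <- extract_growth_parameters(tl, events, t_start = tl$times[1],
                                  n_probe = n_probe)
  wr(cbind(data.frame(b_r = gp$b_r, r_grow_pre = gp$r_grow_pre,
                      r_grow_post = gp$r_grow_post), gp$bins),
     "growth_params")
  # growth-model ensemble
  arena <- make_arena(comb$tree)
  sims_g <- lapply(seq_len(n_growth), function(i)
    simulate_development(arena, gp, seed = seed + 10L + i))
  finals <- lapply(sims_g, function(s) s$trees[[length(s$trees)]])
  growth <- wr(data.frame(
    run = seq_len(n_growth),
    N = vapply(finals, function(t) sum(is_branch_point(t)), integer(1)),
    L = vapply(finals, total_length, numeric(1)),
    S = vapply(finals, spanning_area, numeric(1))), "growth_ensemble")
  # calcium / kinematics
  peri <- make_peristalsis(peristalsis_params(), seed = seed + 20L)
  ctr <- lapply(peri$trajectories, contraction_rate)
  drr <- lapply(peri$traces, delta_r_over_r)
  al <- align_and_average(ctr, drr)
  wr(data.frame(offset = al$offset, mean_contraction = al$mean_contraction,
                mean_drr0 = al$mean_drr0, n_trials = al$n_trials),
     "calcium_aligned")
  manifest <- data.frame(
    stage = c("pipeline", "scaling", "growth"),
    seed = c(seed, seed + 2L, seed + 11L),
    note = c(sprintf("package combgrow %s",
                     as.character(utils::packageVersion("combgrow"))),
             sprintf("n_sims=%d", n_sims),
             sprintf("n_growth=%d n_probe=%d%s", n_growth, n_probe,
                     if (n_probe < 100000) " (scaled down)" else "")))
  wr(manifest, "manifest")
  invisible(list(morphometrics = morpho, schemes = schemes,
                 dynamics = summ, growth = growth,
                 scaling = fit, peak_lag = al$peak_lag))
}
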