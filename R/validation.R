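# Ensemble-level validation harnesses chaining the synthetic generators,
# the growth model and the scaling analysis. Used by the test suite and by
# scripts/acceptance.R.

#' Synthetic growth arenas
#'
#' Builds a set of growth arenas from independently drawn synthetic comb
#' morphologies (main branch around 40 µm, 16-20 lateral branches with
#' median length 9 µm — the embryonic spanning-field regime).
#'
#' @param n_arenas number of arenas.
#' @param seed integer seed.
#' @return list of [growth_arena] objects.
#' @export
make_arena_set <- function(n_arenas = 10, seed = 1) {
  set.seed(seed)
  cfg <- data.frame(mb = stats::runif(n_arenas, 38, 42),
                    nl = sample(16:20, n_arenas, replace = TRUE),
                    sd = sample.int(1e6, n_arenas))
  lapply(seq_len(n_arenas), function(i) {
    cp <- comb_params(mb_length = cfg$mb[i], n_laterals = cfg$nl[i],
                      so_length_median = 9)
    make_arena(make_comb_tree(cp, seed = cfg$sd[i])$tree)
  })
}

#' Wire-scaling check of the growth model
#'
#' Runs the pure growth model (retraction disabled, iterations over the
#' whole 16-22.5 h window) for `n_runs` seeds distributed over a set of
#' synthetic arenas, records every frame with at least `min_bp` branch
#' points as an area-normalised (N, L) pair (total length rescaled to a
#' 100 µm² spanning field via the convex spanning area), and fits the
#' wire-optimality relation L vs sqrt(N). Frames below `min_bp` are the
#' polarisation stage, where a single main branch dominates and the
#' spanning field is degenerate.
#'
#' @param n_runs number of simulations.
#' @param arenas list of [growth_arena]s (default: [make_arena_set()]).
#' @param n_probe probe points per iteration.
#' @param b_r branch additions per iteration.
#' @param min_bp minimum branch points for a frame to enter the fit.
#' @param seed integer seed.
#' @return list with `fit` (from [fit_scaling()]), `table` (the (N, L)
#'   pairs) and `sims` metadata.
#' @export
growth_scaling_ensemble <- function(n_runs = 50, arenas = NULL,
                                    n_probe = 5000, b_r = 12,
                                    min_bp = 10, seed = 1) {
  if (is.null(arenas)) arenas <- make_arena_set(seed = seed)
  p <- growth_params(b_r = b_r, n_probe = n_probe,
                     retraction_times = numeric(0))
  rows <- list()
  for (s in seq_len(n_runs)) {
    arena <- arenas[[(s - 1L) %% length(arenas) + 1L]]
    sim <- simulate_development(arena, p, seed = seed * 1000L + s)
    for (t in sim$trees) {
      N <- sum(is_branch_point(t))
      if (N < min_bp) next
      S <- spanning_area(t, method = "convex")
      if (S <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        run = s, N = N, L = total_length(t) * sqrt(100 / S), S = S)
    }
  }
  tab <- do.call(rbind, rows)
  list(fit = fit_scaling(tab), table = tab,
       sims = list(n_runs = n_runs, n_probe = n_probe, b_r = b_r,
                   min_bp = min_bp, seed = seed))
}

#' Retraction-scheme comparison study on planted ground truth
#'
#' Builds several independent synthetic comb morphologies, retracts each
#' by the planted mechanism — terminal branches removed uniformly at
#' random — and asks which of the four in-silico retraction schemes
#' reproduces the resulting morphologies best, measured by the
#' 1-Wasserstein distance between per-branch mean-angle distributions
#' pooled over all series (the experimental analysis pools its branch
#' populations across cells in the same way, which keeps the sampling
#' noise floor of the distance well below the schemes' biases). If the
#' schemes are implemented correctly the random scheme must come out
#' closest, since it is the generating mechanism.
#'
#' @param n_series number of independent pre/post series.
#' @param remove_frac fraction of terminal branches retracted.
#' @param n_reps ensemble size of the random scheme.
#' @param seed integer seed.
#' @return data.frame with mean distances per scheme and `rank_angle`.
#' @export
scheme_comparison_study <- function(n_series = 8, remove_frac = 0.5,
                                    n_reps = 10, seed = 1) {
  schemes <- c("shortest_first", "low_angle_first", "high_blo_first",
               "random")
  pool_target <- pool_len_t <- numeric(0)
  pool_sim <- pool_len_s <- stats::setNames(
    rep(list(numeric(0)), length(schemes)), schemes)
  branch_angles <- function(t) {
    br <- branch_table(find_main_branch(t))
    list(ang = br$mean_angle[!is.na(br$mean_angle)], len = br$length)
  }
  for (i in seq_len(n_series)) {
    sdi <- seed * 100L + i
    comb <- make_comb_tree(comb_params(n_laterals = 18, ho_rate = 2.5,
                                       mb_length = 60), seed = sdi)
    pre <- comb$tree
    n_term <- nrow(dissect_terminal_branches(pre)) - 1L
    n_remove <- round(remove_frac * n_term)
    post <- apply_retraction_scheme(pre, "random", n_remove, n_reps = 1,
                                    seed = sdi + 11L)[[1]]
    ba <- branch_angles(post)
    pool_target <- c(pool_target, ba$ang)
    pool_len_t <- c(pool_len_t, ba$len)
    for (sc in schemes) {
      trees <- if (sc == "random")
        apply_retraction_scheme(pre, sc, n_remove, n_reps = n_reps,
                                seed = sdi + 23L)
      else list(apply_retraction_scheme(pre, sc, n_remove))
      for (t in trees) {
        ba <- branch_angles(t)
        pool_sim[[sc]] <- c(pool_sim[[sc]], ba$ang)
        pool_len_s[[sc]] <- c(pool_len_s[[sc]], ba$len)
      }
    }
  }
  out <- data.frame(
    scheme = schemes,
    angle_emd = vapply(schemes, function(sc)
      emd1d(pool_sim[[sc]], pool_target), numeric(1)),
    length_emd = vapply(schemes, function(sc)
      emd1d(pool_len_s[[sc]], pool_len_t), numeric(1)))
  out$rank_angle <- rank(out$angle_emd, ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Post-retraction orientation-angle shift of the growth model
#'
#' End-to-end check of the retraction stage: a synthetic comb fixture is
#' turned into a time-lapse with planted events, the growth model is
#' parameterised from the tracked dynamics ([extract_growth_parameters()]),
#' an ensemble of simulations with stochastic retraction is run on the
#' arena of the peak-complexity frame, and the pooled per-branch mean
#' orientation angles of the simulated trees are compared just before the
#' end of the extension phase (19.5 h) and at the end of development.
#' Random removal of a fixed cable length preferentially eliminates the
#' short, flat-angle branches, so the median angle should increase.
#'
#' Several independent comb fixtures are pooled (as the experimental
#' analysis pools its time series), each contributing its own extracted
#' parameter set and simulation ensemble.
#'
#' @param n_fixtures number of independent comb time-lapse fixtures.
#' @param n_runs simulations per fixture.
#' @param n_probe probe points per iteration.
#' @param seed integer seed.
#' @return list with `median_pre`, `median_post`, `shift` (degrees),
#'   pooled angle vectors and the per-fixture extracted [growth_params()].
#' @export
retraction_angle_shift <- function(n_fixtures = 3, n_runs = 8,
                                   n_probe = 5000, seed = 1) {
  a_pre <- a_post <- numeric(0)
  gps <- vector("list", n_fixtures)
  angles_of <- function(t) branch_table(find_main_branch(t))$mean_angle
  for (f in seq_len(n_fixtures)) {
    fseed <- seed * 100L + f * 7L
    young <- make_comb_tree(comb_params(n_laterals = 12, ho_rate = 1.2),
                            seed = fseed)
    tl <- make_timelapse(timelapse_params(), base = young$tree,
                         seed = fseed + 1L)
    ev <- track_series(tl)
    gp <- extract_growth_parameters(tl, ev, t_start = 16,
                                    n_probe = n_probe)
    gps[[f]] <- gp
    N <- vapply(tl$trees, function(t) sum(is_branch_point(t)), integer(1))
    arena <- make_arena(tl$trees[[which.max(N)]])
    sims <- lapply(seq_len(n_runs), function(s)
      simulate_development(arena, gp, seed = fseed * 1000L + s))
    # before retraction = each run's peak-complexity frame
    a_pre <- c(a_pre, unlist(lapply(sims, function(sim) {
      Ns <- vapply(sim$trees, function(t) sum(is_branch_point(t)),
                   integer(1))
      angles_of(sim$trees[[which.max(Ns)]])
    })))
    a_post <- c(a_post, unlist(lapply(sims, function(sim)
      angles_of(sim$trees[[length(sim$trees)]]))))
  }
  m_pre <- stats::median(a_pre, na.rm = TRUE)
  m_post <- stats::median(a_post, na.rm = TRUE)
  list(median_pre = m_pre, median_post = m_post, shift = m_post - m_pre,
       angles_pre = a_pre, angles_post = a_post, params = gps)
}
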