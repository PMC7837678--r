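#' Bootstrap test for a difference of medians
#'
#' Empirical two-sided test of the difference between the medians of two
#' samples, with no distributional assumptions. The null distribution is
#' built by pooled resampling: both samples are drawn with replacement from
#' the pooled data (sizes preserved) and the median difference recomputed
#' `n_boot` times; the p-value is the add-one-corrected fraction of null
#' differences at least as extreme in absolute value as the observed one.
#'
#' Two constant, identical samples are degenerate and return `p = 1`.
#'
#' @param a,b numeric samples (non-empty).
#' @param n_boot number of bootstrap resamples (>= 1000).
#' @param seed optional integer seed for reproducibility.
#' @return list with `difference` (median(a) - median(b)), `p_value`,
#'   and `n_boot`.
#' @export
bootstrap_median_test <- function(a, b, n_boot = 10000, seed = NULL) {
  stopifnot(length(a) > 0, length(b) > 0, n_boot >= 1000)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  obs <- stats::median(a) - stats::median(b)
  pool <- c(a, b)
  na <- length(a); nb <- length(b)
  if (max(pool) == min(pool))
    return(list(difference = 0, p_value = 1, n_boot = n_boot))
  # resampling from a fixed pool: the null medians are order statistics of
  # the drawn indices into the sorted pool, so one integer radix sort per
  # resample matrix suffices
  sp <- sort(pool)
  n_pool <- na + nb
  med_of <- function(n) {
    I <- matrix(sample.int(n_pool, n_boot * n, replace = TRUE),
                nrow = n_boot)
    o <- order(rep.int(seq_len(n_boot), n), as.vector(I),
               method = "radix")
    Is <- matrix(as.vector(I)[o], nrow = n_boot, byrow = TRUE)
    if (n %% 2L == 1L) sp[Is[, (n + 1L) / 2L]]
    else (sp[Is[, n / 2L]] + sp[Is[, n / 2L + 1L]]) / 2
  }
  null_diff <- med_of(na) - med_of(nb)
  p <- (1 + sum(abs(null_diff) >= abs(obs) - 1e-12)) / (n_boot + 1)
  list(difference = obs, p_value = p, n_boot = n_boot)
}
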