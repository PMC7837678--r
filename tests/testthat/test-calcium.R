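test_that("contraction normalisation maps distension to 0 and maximal
           contraction to 1", {
  traj <- list(times = (0:4) * 0.2,
               central = cbind(rep(0, 5), 0),
               anterior = cbind(c(-10, -10, -5, -10, -10), 0),
               posterior = cbind(c(10, 10, 5, 10, 10), 0))
  out <- contraction_rate(traj)
  expect_equal(out$contraction, c(0, 0, 1, 0, 0))
  # a linear ramp in distance maps to a reversed linear ramp
  traj2 <- list(times = (0:4) * 0.2,
                central = cbind(rep(0, 5), 0),
                anterior = cbind(-(10 - 0:4), 0),
                posterior = cbind(10 - 0:4, 0))
  expect_equal(contraction_rate(traj2)$contraction, (0:4) / 4)
  traj3 <- traj; traj3$anterior[, 1] <- -10; traj3$posterior[, 1] <- 10
  expect_error(contraction_rate(traj3), "constant")
})

test_that("fold change follows the ratio formula with a 5-frame baseline", {
  tr <- list(times = (0:9) * 0.2, f_green = rep(50, 10),
             f_red = rep(100, 10))
  expect_equal(delta_r_over_r(tr)$drr0, rep(0, 10))
  tr2 <- tr; tr2$f_green[6:10] <- 100   # ratio doubles after baseline
  expect_equal(delta_r_over_r(tr2)$drr0, c(rep(0, 5), rep(1, 5)))
  tr3 <- tr2; tr3$f_red[7] <- 0
  expect_true(is.na(delta_r_over_r(tr3)$drr0[7]))
  # invariant to a common rescale of both channels
  tr4 <- tr2; tr4$f_green <- tr4$f_green * 3.7; tr4$f_red <- tr4$f_red * 3.7
  expect_equal(delta_r_over_r(tr4)$drr0, delta_r_over_r(tr2)$drr0)
})

test_that("alignment centres trials on maximal contraction", {
  peri <- make_peristalsis(peristalsis_params(pos_noise = 0, r = 0.999),
                           seed = 1)
  ctr <- lapply(peri$trajectories, contraction_rate)
  drr <- lapply(peri$traces, delta_r_over_r)
  al <- align_and_average(ctr, drr)
  i0 <- which(al$offset == 0)
  expect_equal(al$mean_contraction[i0], 1, tolerance = 1e-6)
  expect_equal(al$peak_lag, peri$lag_s)
  # identical trials: mean equals the trial, SEM is zero
  al2 <- align_and_average(ctr[c(1, 1, 1, 1, 1)], drr[c(1, 1, 1, 1, 1)])
  ok <- !is.na(al2$sem_contraction)
  expect_true(all(al2$sem_contraction[ok] == 0))
  # shift equivariance: padding a trial with early frames changes nothing
  ctr_s <- ctr; drr_s <- drr
  ctr_s[[1]]$contraction <- c(rep(0, 3), ctr_s[[1]]$contraction)
  ctr_s[[1]]$times <- c(-(3:1) * 0.2, ctr_s[[1]]$times)
  drr_s[[1]]$drr0 <- c(rep(0, 3), drr_s[[1]]$drr0)
  drr_s[[1]]$times <- ctr_s[[1]]$times
  al3 <- align_and_average(ctr_s, drr_s)
  expect_equal(al3$peak_lag, al$peak_lag)
})

test_that("planted lag and coupling strength are recovered", {
  peri <- make_peristalsis(seed = 3)
  ctr <- lapply(peri$trajectories, contraction_rate)
  drr <- lapply(peri$traces, delta_r_over_r)
  al <- align_and_average(ctr, drr)
  expect_equal(al$peak_lag, 0.2)
  rs <- mapply(function(c1, d1)
    stats::cor(c1$contraction, d1$drr0, use = "complete"), ctr, drr)
  expect_lt(abs(mean(rs) - peri$r), 0.06)
})
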