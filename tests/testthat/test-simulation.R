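test_that("the synthetic input peaks where configured and stays consistent", {
  inp <- synth_input(peak_kbq_ml = 40, peak_time_min = 1, t_max_min = 90)
  ipk <- which.max(inp$whole_blood)
  expect_equal(inp$time_min[ipk], 1)
  expect_equal(max(inp$whole_blood), 40)
  expect_true(all(inp$whole_blood >= 0))
  expect_true(all(inp$plasma_parent >= 0))

  # the parent curve never exceeds total plasma: Cp * BPR <= Cwb
  p <- attr(inp, "params")
  bpr <- do.call(bpr_model, p$bpr)
  expect_true(all(inp$plasma_parent * bpr_value(bpr, inp$time_min) <=
                    inp$whole_blood + 1e-9))

  expect_equal(synth_input(peak_kbq_ml = 0, t_max_min = 10)$whole_blood,
               rep(0, 601))
  expect_error(synth_input(peak_time_min = -1),
               class = "petsime_invalid_parameter")
})

test_that("frame noise is mean-scaled, seeded and correctly sized", {
  s <- synth_fixture()
  x <- s$tacs$frontal
  prof <- flat_noise_profile(s$sched, 0.05)

  # zero profile is the identity; equal seeds reproduce bit-for-bit
  expect_identical(add_noise(x, flat_noise_profile(s$sched, 0), 1)$activity,
                   x$activity)
  n1 <- add_noise(x, prof, 99)
  expect_identical(add_noise(x, prof, 99)$activity, n1$activity)
  expect_false(identical(add_noise(x, prof, 100)$activity, n1$activity))

  # empirical SD over many draws approaches the requested SD
  draws <- vapply(1:10000, function(i) add_noise(x, prof, i)$activity[30],
                  numeric(1))
  expect_rel_equal(sd(draws), 0.05 * mean(x$activity), 0.02)

  # the default profile boosts short frames
  dp <- noise_profile(s$sched)
  dur <- s$sched$frame_end - s$sched$frame_start
  expect_true(all(dp[dur < 30] == 0.10) && all(dp[dur >= 30] == 0.05))

  expect_error(add_noise(x, rep(0.05, 10), 1),
               class = "petsime_invalid_parameter")
})

test_that("residual profiles average normalized residuals across subjects", {
  sched <- frame_schedule(c(0, 30), c(30, 60), "two")
  obs <- list(list(tac("a", sched, c(11, 9))))
  fit <- list(list(tac("a", sched, c(10, 10))))
  p <- residual_profile(obs, fit)
  expect_equal(as.numeric(p$a), c(0.1, 0.1))
  expect_length(p$a, n_frames(sched))

  # perfect fits give an all-zero profile
  p0 <- residual_profile(obs, obs)
  expect_equal(as.numeric(p0$a), c(0, 0))

  zero <- list(list(tac("a", sched, c(0, 0))))
  expect_error(residual_profile(zero, fit), class = "petsime_degenerate")
})

test_that("zero-noise Monte Carlo recovery is exact and reproducible", {
  s <- synth_fixture()
  prof <- flat_noise_profile(s$sched, 0)
  mc <- monte_carlo_recovery(s$truth, s$inp, s$sched, prof, n_reps = 2,
                             seed = 1, options = fast_options())
  expect_equal(mc$n_failed, 0L)
  expect_true(all(abs(mc$stats$bias_pct) < 0.1))
  expect_true(all(mc$stats$cov_pct < 1e-6, na.rm = TRUE))

  # V_T - V_S = V_ND per replicate, hence exactly for the means
  st <- mc$stats
  for (r in unique(st$region)) {
    m <- function(p) st$mean[st$region == r & st$parameter == p]
    expect_equal(m("V_T") - m("V_S"), m("V_ND"), tolerance = 1e-12)
  }
})

test_that("Monte Carlo runs are seed-reproducible and noise-monotone", {
  s <- synth_fixture()
  opts <- sime_options(n_starts = 1)
  p1 <- flat_noise_profile(s$sched, 0.025)
  p2 <- flat_noise_profile(s$sched, 0.05)
  mc_a <- monte_carlo_recovery(s$truth, s$inp, s$sched, p1, n_reps = 12,
                               seed = 7, options = opts)
  mc_b <- monte_carlo_recovery(s$truth, s$inp, s$sched, p1, n_reps = 12,
                               seed = 7, options = opts)
  expect_identical(mc_a$stats, mc_b$stats)

  mc_c <- monte_carlo_recovery(s$truth, s$inp, s$sched, p2, n_reps = 12,
                               seed = 7, options = opts)
  cov_of <- function(mc, p) mean(mc$stats$cov_pct[mc$stats$parameter == p])
  expect_gt(cov_of(mc_c, "V_ND"), cov_of(mc_a, "V_ND"))
  expect_gt(cov_of(mc_c, "BP_ND"), cov_of(mc_a, "BP_ND"))
})
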