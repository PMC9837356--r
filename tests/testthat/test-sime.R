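test_that("joint SIME recovers a common V_ND from noiseless regions", {
  s <- synth_fixture()
  res <- sime_joint_fit(s$tacs, s$inp)
  expect_false(res$failed)
  expect_rel_equal(res$V_ND_common, 2.35, 1e-3)
  vt <- vapply(res$per_region, function(x) x$dvs$V_T, numeric(1))
  expect_rel_equal(vt, s$truth$V_T, 5e-3)
  # K1 = k2 V_ND by construction in every region
  for (fr in res$per_region)
    expect_equal(fr$rates$K1, fr$rates$k2 * res$V_ND_common,
                 tolerance = 1e-12)
  # no uphill return: pooled cost at the solution is at most the cost at
  # the generating parameters
  setup <- petsime:::sime_setup(s$tacs, s$inp, "none", sime_options())
  truth_par <- c(2.35 * setup$sn, unlist(lapply(attr(s$truth, "rates"),
    function(r) c(r$k2, r$k3, r$k4)), use.names = FALSE))
  cost_truth <- petsime:::sime_cost_fun(setup, 0.05)(truth_par)$value
  expect_lte(res$total_cost, cost_truth + 1e-8)
})

test_that("binding potential is invariant to input-function scaling", {
  # vB = 0 isolates the convolution input, the quantity the scaling
  # property is about (see the matching note in test-fit.R)
  s <- synth_fixture()
  opts <- fast_options()
  rates0 <- lapply(attr(s$truth, "rates"), function(r)
    rate_constants(r$K1, r$k2, r$k3, r$k4, vB = 0))
  tacs0 <- lapply(names(rates0), function(r)
    model_tac(rates0[[r]], s$inp, s$sched, region = r))
  r1 <- sime_joint_fit(tacs0, s$inp, vB = 0, options = opts)
  inp2 <- input_function(s$inp$time_min, 2 * s$inp$whole_blood,
                         2 * s$inp$plasma_parent, "synthetic")
  r2 <- sime_joint_fit(tacs0, inp2, vB = 0, options = opts)
  expect_rel_equal(r2$V_ND_common, r1$V_ND_common / 2, 1e-3)
  for (nm in names(r1$per_region)) {
    expect_rel_equal(r2$per_region[[nm]]$dvs$V_T,
                     r1$per_region[[nm]]$dvs$V_T / 2, 1e-3)
    expect_rel_equal(r2$per_region[[nm]]$dvs$BP_ND,
                     r1$per_region[[nm]]$dvs$BP_ND, 1e-3)
  }
})

test_that("six identical regions reduce to the single-region fit", {
  s <- synth_fixture()
  copies <- lapply(1:6, function(i) {
    x <- s$tacs$frontal
    x$region <- paste0("copy", i)
    x
  })
  res <- sime_joint_fit(copies, s$inp, options = fast_options())
  vts <- vapply(res$per_region, function(x) x$dvs$V_T, numeric(1))
  expect_lt(diff(range(vts)) / mean(vts), 1e-6)
  single <- fit_2tcm(s$tacs$frontal, s$inp, weights = "none",
                     options = fast_options())
  expect_rel_equal(res$V_ND_common, single$dvs$V_ND, 5e-3)
})

test_that("grid-search SIME brackets the optimizer estimate", {
  s <- synth_fixture()
  opts <- fast_options()
  gs <- sime_grid_search(s$tacs, s$inp, grid = seq(1.5, 3.5, by = 0.05),
                         options = opts)
  expect_equal(gs$V_ND_common, 2.35, tolerance = 1e-9)

  # oracle equivalence on noiseless data: within one grid step
  opt <- sime_joint_fit(s$tacs, s$inp, options = opts)
  expect_lt(abs(gs$V_ND_common - opt$V_ND_common), 0.05 + 1e-9)

  # single-point grid returns that point with profile fits
  g1 <- sime_grid_search(s$tacs, s$inp, grid = 2.0, options = opts)
  expect_equal(g1$V_ND_common, 2.0)
  expect_equal(length(g1$grid_cost), 1L)

  # a grid excluding the optimum warns about the endpoint minimum
  expect_warning(sime_grid_search(s$tacs, s$inp,
                                  grid = seq(0.5, 1.5, by = 0.25),
                                  options = opts),
                 "endpoint")
})

test_that("ROI-subset analysis enumerates combinations and stays stable", {
  s <- synth_fixture()
  opts <- fast_options()
  r5 <- roi_subset_vnd(s$tacs, s$inp, k = 5, options = opts)
  expect_equal(nrow(r5$table), 6)
  expect_rel_equal(r5$table$V_ND, rep(2.35, 6), 1e-3)

  r4 <- roi_subset_vnd(s$tacs, s$inp, k = 4, options = sime_options(n_starts = 1))
  expect_equal(nrow(r4$table), 15)
  expect_rel_equal(r4$mean_vnd, 2.35, 1e-3)

  expect_warning(roi_subset_vnd(s$tacs[1:3], s$inp, k = 3, options = opts),
                 "three regions")
  expect_error(roi_subset_vnd(s$tacs, s$inp, k = 2),
               class = "petsime_invalid_parameter")
})

test_that("SIME input validation catches mismatched regions", {
  s <- synth_fixture()
  short <- truncate_tac(s$tacs$frontal, 60)
  expect_error(sime_joint_fit(list(s$tacs$temporal, short), s$inp),
               class = "petsime_invalid_tac")
  expect_warning(sime_joint_fit(s$tacs[1:3], s$inp,
                                options = sime_options(n_starts = 1)),
                 "3 ROI")
})
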