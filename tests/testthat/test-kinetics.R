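test_that("biexponential IRF matches closed forms and an ODE oracle", {
  # 1TCM reduction: k3 = k4 = 0 gives a single exponential
  irf1 <- biexp_irf(rate_constants(0.2, 0.1, 0, 0))
  t <- seq(0, 60, by = 0.5)
  expect_equal(eval_irf(irf1, t), 0.2 * exp(-0.1 * t), tolerance = 1e-12)
  expect_equal(irf1$phi1 + irf1$phi2, 0.2, tolerance = 1e-9)

  # IRF(0) = K1 for any admissible rates
  for (r in list(frontal_rates(), rate_constants(0.1, 0.05, 0.01, 0.002),
                 rate_constants(1.5, 0.9, 0.4, 0.3)))
    expect_equal(eval_irf(biexp_irf(r), 0), r$K1, tolerance = 1e-12)

  # equal decay roots (only possible with k3 = 0, k2 = k4): degenerate form
  irfd <- biexp_irf(rate_constants(0.2, 0.1, 0, 0.1))
  expect_true(irfd$degenerate)
  expect_equal(eval_irf(irfd, t), 0.2 * exp(-0.1 * t), tolerance = 1e-9)

  # independent oracle: direct numeric integration of the compartment ODEs
  r <- frontal_rates()
  rhs <- function(t, y, p) {
    list(c(-(p$k2 + p$k3) * y[1] + p$k4 * y[2],
           p$k3 * y[1] - p$k4 * y[2]))
  }
  sol <- deSolve::lsoda(c(C1 = r$K1, C2 = 0), c(0, 1, 10, 60), rhs, r,
                        rtol = 1e-10, atol = 1e-12)
  irf <- biexp_irf(r)
  expect_rel_equal(eval_irf(irf, c(1, 10, 60)),
                   sol[-1, "C1"] + sol[-1, "C2"], 1e-6)
})

test_that("IRF time-integral equals the total distribution volume", {
  set.seed(7)
  for (i in 1:10) {
    r <- rate_constants(K1 = runif(1, 0.05, 0.5), k2 = runif(1, 0.02, 0.3),
                        k3 = runif(1, 0, 0.4), k4 = runif(1, 0.01, 0.2))
    irf <- biexp_irf(r)
    vt <- derive_dvs(r)$V_T
    expect_rel_equal(irf$phi1 / irf$theta1 + irf$phi2 / irf$theta2, vt, 1e-9)
    quad <- integrate(function(t) eval_irf(irf, t), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_rel_equal(quad, vt, 1e-6)
  }
})

test_that("macro-parameters follow the distribution-volume identities", {
  d <- derive_dvs(frontal_rates())
  expect_equal(d$V_ND, 2.35, tolerance = 1e-10)
  expect_equal(d$V_T, 14.30, tolerance = 1e-10)
  expect_equal(d$V_S, 11.95, tolerance = 1e-10)
  expect_equal(d$BP_ND, d$V_S / d$V_ND, tolerance = 1e-12)
  expect_equal(d$V_T, d$V_ND + d$V_S, tolerance = 1e-12)

  # k3 = 0 collapses to the non-displaceable volume
  d0 <- derive_dvs(rate_constants(0.3, 0.12, 0, 0.05))
  expect_equal(d0$BP_ND, 0)
  expect_equal(d0$V_T, d0$V_ND)
  # K1 = k2 pins V_ND at 1
  expect_equal(derive_dvs(rate_constants(0.1, 0.1, 0.3, 0.1))$V_ND, 1)

  expect_error(derive_dvs(rate_constants(0.2, 0.1, 0.1, 0)),
               class = "petsime_unbounded_vt")
  expect_error(rate_constants(0.2, -0.1, 0.1, 0.05),
               class = "petsime_invalid_parameter")
  expect_error(biexp_irf(rate_constants(0.2, 0, 0.1, 0.05)),
               class = "petsime_invalid_parameter")
})

test_that("the modelled TAC behaves like the compartment model", {
  s <- synth_fixture()
  r <- frontal_rates()

  # zero input -> zero TAC; pure-blood input -> vB * C_wb per frame
  tg <- s$inp$time_min
  zero <- input_function(tg, rep(0, length(tg)), rep(0, length(tg)),
                         "synthetic")
  expect_equal(model_tac(r, zero, s$sched)$activity, rep(0, 52))
  blood10 <- input_function(tg, rep(10, length(tg)), rep(0, length(tg)),
                            "synthetic")
  expect_equal(model_tac(r, blood10, s$sched)$activity, rep(0.5, 52),
               tolerance = 1e-12)

  # linearity: doubling both input curves doubles every frame value
  m1 <- model_tac(r, s$inp, s$sched)
  inp2 <- input_function(tg, 2 * s$inp$whole_blood, 2 * s$inp$plasma_parent,
                         "synthetic")
  expect_equal(model_tac(r, inp2, s$sched)$activity, 2 * m1$activity,
               tolerance = 1e-12)

  # constant unit plasma input saturates at (1 - vB) V_T
  irf <- biexp_irf(r)
  t_inf <- 20 / irf$theta2
  t_end <- ceiling(t_inf / 10) * 10
  tgl <- seq(0, t_end, by = 1 / 6)
  const <- input_function(tgl, rep(0, length(tgl)), rep(1, length(tgl)),
                          "synthetic")
  late <- frame_schedule((t_end - 10) * 60, t_end * 60, "late")
  mlate <- model_tac(r, const, late, grid_dt_s = 10)
  expect_rel_equal(mlate$activity, 0.95 * derive_dvs(r)$V_T, 0.01)

  # frame averages converge to midpoint samples on short smooth frames
  r0 <- rate_constants(r$K1, r$k2, r$k3, r$k4, vB = 0)
  five_s <- frame_schedule(seq(60, 115, by = 5), seq(65, 120, by = 5), "5s")
  fa <- model_tac(r0, s$inp, five_s, mode = "frame_average")
  mp <- model_tac(r0, s$inp, five_s, mode = "midpoint")
  expect_rel_equal(fa$activity, mp$activity, 1e-3)

  # schedule beyond the input support is refused
  expect_error(model_tac(r, s$inp, frame_schedule(0, 100 * 60, "long")),
               class = "petsime_coverage_error")
})

test_that("macro-parameters from the fitted IRF integral match derive_dvs", {
  s <- synth_fixture()
  set.seed(11)
  for (i in 1:5) {
    r <- rate_constants(K1 = runif(1, 0.1, 0.4), k2 = runif(1, 0.05, 0.2),
                        k3 = runif(1, 0.01, 0.3), k4 = runif(1, 0.02, 0.1))
    irf <- biexp_irf(r)
    expect_rel_equal(irf$phi1 / irf$theta1 + irf$phi2 / irf$theta2,
                     derive_dvs(r)$V_T, 1e-9)
  }
})
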