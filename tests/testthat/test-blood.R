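# serial blood-sampling times used throughout (2.5-180 min protocol)
serial_times <- c(2.5, 7, 12, 20, 30, 45, 60, 90, 120, 180)

test_that("biexponential BPR fitting recovers known curves", {
  # constant ratio: plateau fit with zero residual
  bs <- blood_samples(serial_times, whole_blood = 0.85 * (10:1),
                      plasma = 10:1)
  m <- fit_bpr(bs)
  expect_equal(bpr_value(m, serial_times), rep(0.85, 10), tolerance = 1e-6)
  expect_lt(attr(m, "rss"), 1e-10)

  # noiseless self-consistency: 0.5 exp(-0.1 t) + 0.7
  y <- 0.5 * exp(-0.1 * serial_times) + 0.7
  bs2 <- blood_samples(serial_times, whole_blood = y, plasma = rep(1, 10))
  m2 <- fit_bpr(bs2)
  expect_lt(attr(m2, "rss"), 1e-10)
  expect_rel_equal(m2$A1, 0.5, 1e-4)
  expect_rel_equal(m2$lam1, 0.1, 1e-4)
  expect_rel_equal(m2$A2, 0.7, 1e-4)
  expect_lt(abs(m2$lam2), 1e-4)

  expect_error(fit_bpr(blood_samples(c(1, 5, 10, 20), 1:4, c(1, 1, 0, 1))),
               class = "petsime_invalid_sample")
  expect_error(fit_bpr(blood_samples(c(1, 5, 10), 1:3, rep(1, 3))),
               class = "petsime_insufficient_data")
})

test_that("Hill parent-fraction fitting respects its functional form", {
  true <- hill_model(a = 0.1, b = 1.5, c = 50)
  bs <- blood_samples(serial_times, 1, 1,
                      parent_fraction = hill_value(true, serial_times))
  m <- fit_parent_fraction(bs)
  expect_equal(hill_value(m, 0), 1)
  expect_rel_equal(c(m$a, m$b, m$c), c(0.1, 1.5, 50), 1e-3)

  # unmetabolized everywhere: fitted curve is identically 1
  bs1 <- blood_samples(serial_times, 1, 1, parent_fraction = rep(1, 10))
  m1 <- fit_parent_fraction(bs1)
  expect_equal(hill_value(m1, serial_times), rep(1, 10), tolerance = 1e-8)

  # monotone non-increasing for admissible parameters
  set.seed(3)
  tt <- seq(0, 180, by = 0.5)
  for (i in 1:10) {
    h <- hill_model(runif(1), runif(1, 0.2, 4), runif(1, 1, 500))
    f <- hill_value(h, tt)
    expect_true(all(diff(f) <= 1e-12))
    expect_true(all(f >= h$a - 1e-12 & f <= 1))
  }

  expect_error(fit_parent_fraction(blood_samples(1:3, 1, 1,
                                                 parent_fraction = c(1, .5, .2))),
               class = "petsime_insufficient_data")
})

test_that("metabolite correction composes BPR and parent fraction", {
  s <- synth_fixture()
  wb <- input_function(s$inp$time_min, s$inp$whole_blood, provenance = "IDIF")

  # identity models leave the whole-blood curve untouched
  ident <- metabolite_correct(wb, bpr_model(1, 0, 0, 0), hill_model(1, 1, 1))
  expect_equal(ident$plasma_parent, wb$whole_blood)

  # constant BPR 2 and fraction 0.5 quarter the curve
  m <- metabolite_correct(wb, bpr_model(2, 0, 0, 0),
                          hill_model(0.5, 1, 1e-12))
  expect_equal(m$plasma_parent[-1], wb$whole_blood[-1] / 4, tolerance = 1e-9)

  # pointwise spot check at t = 30 min with non-trivial fitted models
  bprm <- bpr_model(0.5, 0.7, 0.1, 0)
  hillm <- hill_model(0.1, 1.5, 50)
  mc <- metabolite_correct(wb, bprm, hillm)
  i30 <- which.min(abs(wb$time_min - 30))
  expect_equal(mc$plasma_parent[i30],
               wb$whole_blood[i30] /
                 (0.5 * exp(-0.1 * 30) + 0.7) *
                 (1 - 0.9 * 30^1.5 / (50 + 30^1.5)),
               tolerance = 1e-9)

  # linearity: scaling the whole-blood curve scales the corrected curve
  wb2 <- input_function(wb$time_min, 3 * wb$whole_blood, provenance = "IDIF")
  expect_equal(metabolite_correct(wb2, bprm, hillm)$plasma_parent,
               3 * mc$plasma_parent, tolerance = 1e-12)
})

test_that("IDIF venous scaling uses the least-squares scalar", {
  tgrid <- seq(0, 95, by = 0.05)
  shape <- exp(-0.02 * tgrid) * 3
  idif <- input_function(tgrid, shape, 0.8 * shape, provenance = "IDIF")

  at <- function(x, tm) approx(x$time_min, x$whole_blood, tm)$y
  u <- at(idif, c(45, 60, 90))

  # venous samples equal to the IDIF leave it unchanged (s = 1)
  ven_eq <- blood_samples(c(45, 60, 90), u, u / 0.8, site = "venous")
  s1 <- scale_idif(idif, ven_eq)
  expect_equal(attr(s1, "scale_factor"), 1, tolerance = 1e-12)
  expect_equal(s1$whole_blood, idif$whole_blood)

  # doubled samples double the curve
  ven2 <- blood_samples(c(45, 60, 90), 2 * u, 2 * u, site = "venous")
  expect_equal(attr(scale_idif(idif, ven2), "scale_factor"), 2,
               tolerance = 1e-12)

  # closed-form check: s = sum(v u) / sum(u^2)
  idif3 <- input_function(seq(0, 90, by = 15),
                          c(0.5, 0.9, 1.2, 1.5, 1.0, 0.8, 0.7),
                          provenance = "IDIF")
  ven3 <- blood_samples(c(45, 60, 90), c(3.1, 2.0, 1.4), c(4, 3, 2),
                        site = "venous")
  s3 <- scale_idif(idif3, ven3)
  expect_equal(attr(s3, "scale_factor"), 7.63 / 3.74, tolerance = 1e-12)

  # idempotent: rescaling an already-scaled curve gives s = 1
  again <- scale_idif(s3, ven3)
  expect_equal(attr(again, "scale_factor"), 1, tolerance = 1e-12)

  # plasma-parent curve is scaled along with whole blood
  sc <- scale_idif(idif, ven2)
  expect_equal(sc$plasma_parent, 2 * idif$plasma_parent)

  expect_error(scale_idif(idif, blood_samples(30, 1, 1, site = "venous")),
               class = "petsime_scaling_error")
  zero <- input_function(tgrid, rep(0, length(tgrid)), provenance = "IDIF")
  expect_error(scale_idif(zero, ven_eq), class = "petsime_degenerate")
})

test_that("venous-arterial agreement matches ordinary least squares", {
  # identical measurements: the identity line
  a <- venous_arterial_agreement(1:8, 1:8)
  expect_equal(a$slope, 1, tolerance = 1e-12)
  expect_equal(a$intercept, 0, tolerance = 1e-12)
  expect_equal(a$r_squared, 1, tolerance = 1e-12)
  expect_equal(a$p_slope_vs_one, 1)

  # exact doubling: slope 2 detected as different from 1
  b <- venous_arterial_agreement(2 * (1:10), 1:10)
  expect_equal(b$slope, 2, tolerance = 1e-12)
  expect_equal(b$r_squared, 1, tolerance = 1e-12)
  expect_lt(b$p_slope_vs_one, 1e-6)

  # noisy pairs: agree with a hand-built regression t-test
  set.seed(5)
  x <- seq(0.5, 1.5, length.out = 10)
  y <- 0.94 * x + 0.06 + rnorm(10, 0, 0.03)
  g <- venous_arterial_agreement(y, x)
  fit <- lm(y ~ x)
  se <- summary(fit)$coefficients[2, 2]
  tval <- (coef(fit)[2] - 1) / se
  expect_equal(g$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(g$p_slope_vs_one,
               unname(2 * pt(abs(tval), 8, lower.tail = FALSE)),
               tolerance = 1e-12)
  expect_equal(g$r_squared, summary(fit)$r.squared, tolerance = 1e-12)

  expect_error(venous_arterial_agreement(1:2, 1:2),
               class = "petsime_insufficient_data")
  expect_error(venous_arterial_agreement(1:4, rep(2, 4)),
               class = "petsime_degenerate")
})
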