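test_that("Moore curve evaluates its closed form and clamps at zero", {
  p <- moore_params(a = 1, b = 1, c = 1, d = 0.1)
  expect_equal(as.numeric(moore_performance(0, p)), 0)
  # (1 - e^-1) - (e^0.1 - 1), frozen from direct evaluation
  expect_equal(as.numeric(moore_performance(1, p)), 0.5269496, tolerance = 1e-6)

  # decline term dominates: raw value negative, clamped and flagged
  p2 <- moore_params(a = 1, b = 1, c = 5, d = 1)
  v <- moore_performance(3, p2)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "clamped"))
  raw <- moore_performance(3, p2, clamp = FALSE)
  expect_lt(as.numeric(raw), 0)

  expect_error(moore_params(a = -1, b = 1, c = 1, d = 1), "positive")
  expect_error(moore_performance(-1, p), "non-negative")
})

test_that("Siler hazard evaluates its three components", {
  p <- siler_params(a1 = 1, b1 = 1, a2 = 0.5, a3 = 0.01, b3 = 0.5)
  expect_equal(siler_hazard(0, p), p$a1 + p$a2 + p$a3)
  expect_equal(siler_hazard(2, p), 0.6625181, tolerance = 1e-6)
  flat <- siler_params(a1 = 0, b1 = 1, a2 = 0.7, a3 = 0, b3 = 1)
  expect_equal(siler_hazard(c(0, 1, 10, 100), flat), rep(0.7, 4))
  expect_error(siler_params(a1 = -1, b1 = 1, a2 = 0, a3 = 0, b3 = 0),
               "non-negative")
})

test_that("age-dependent mature hazard turns the Siler form into Moore's", {
  expect_equal(siler_equivalent_a2(0, a1 = 2, b1 = 1, a3 = 0.3, b3 = 0.5),
               -(2 + 0.3))
  # a3 = 0: a2(t) = 1 - 2 e^-t, zero at t = log(2)
  expect_equal(siler_equivalent_a2(log(2), a1 = 1, b1 = 1, a3 = 0, b3 = 1), 0)

  # substitution reproduces the Moore double-exponential, both sides
  # evaluated independently
  a1 <- 2; b1 <- 0.5; a3 <- 0.1; b3 <- 0.3; t <- 4
  a2t <- siler_equivalent_a2(t, a1, b1, a3, b3)
  p <- siler_params(a1 = a1, b1 = b1, a2 = 0, a3 = a3, b3 = b3)
  lhs <- siler_hazard(t, p, a2 = a2t)
  rhs <- a1 * (1 - exp(-b1 * t)) + a3 * (1 - exp(b3 * t))
  expect_equal(lhs, rhs, tolerance = 1e-14)
  expect_equal(rhs, 2 * (1 - exp(-2)) + 0.1 * (1 - exp(1.2)), tolerance = 1e-12)
})

test_that("Siler-Moore bridge identity holds across random parameter sets", {
  set.seed(101)
  t <- seq(0, 20, length.out = 11)
  for (i in 1:200) {
    ps <- random_siler_set()
    a2t <- siler_equivalent_a2(t, ps$a1, ps$b1, ps$a3, ps$b3)
    sp <- siler_params(a1 = ps$a1, b1 = ps$b1, a2 = 0, a3 = ps$a3, b3 = ps$b3)
    lhs <- siler_hazard(t, sp, a2 = a2t)
    rhs <- ps$a1 * (-expm1(-ps$b1 * t)) + ps$a3 * (-expm1(ps$b3 * t))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("growth rate and senescence factors match their closed forms", {
  expect_equal(imap_growth_rate(0, 0.5, 0.2), 0.5)
  expect_equal(imap_growth_rate(1 / 0.2, 0.5, 0.2), 0.5 / exp(1))
  expect_equal(imap_growth_rate(10, 0.5, 0.2), 0.0676676, tolerance = 1e-6)
  r <- imap_growth_rate(seq(0, 50, by = 5), 0.3, 0.1)
  expect_true(all(diff(r) < 0))

  expect_equal(imap_senescence(100, beta0 = 2, betar = 0.05, td = 100), 0)
  expect_equal(imap_senescence(50, beta0 = 2, betar = 0.05, td = 100),
               1.835830, tolerance = 1e-6)
  expect_equal(imap_senescence(0, beta0 = 1, betar = 2, td = 100), 1,
               tolerance = 1e-10)
  expect_lt(imap_senescence(120, beta0 = 1, betar = 0.05, td = 100), 0)
  expect_error(imap_growth_rate(1, -0.1, 0.2), "positive")
  expect_error(imap_senescence(1, 1, 0.05, -2), "positive")
})

test_that("performance curve vanishes at death and clamps beyond it", {
  p <- imap_params(scale = 3, alpha0 = 0.3, alphar = 0.15, betar = 0.02,
                   td = 90)
  expect_equal(as.numeric(imap_performance(90, p)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(imap_performance(0, p)),
               3 * (1 - exp(-0.02 * 90)), tolerance = 1e-12)
  v <- imap_performance(c(50, 95), p)
  expect_equal(attr(v, "clamped"), c(FALSE, TRUE))
  expect_equal(as.numeric(v[2]), 0)
  expect_lt(imap_performance(95, p, clamp = FALSE), 0)
})

test_that("reduced curve matches direct substitution and the death point", {
  s <- imap_shape(50, 15, 10, td = 1)
  expect_equal(as.numeric(imap_reduced(1, s)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(imap_reduced(0, s)),
               exp(-50 / 15) * (1 - exp(-10)), tolerance = 1e-12)
  expect_equal(as.numeric(imap_reduced(0.5, s)), 0.9914325, tolerance = 1e-6)
})

test_that("dimensional, asymptotic and reduced forms agree on random shapes", {
  set.seed(77)
  for (i in 1:50) {
    s <- random_shape()
    p <- redimensionalize(s)
    t <- seq(0, s$td * 0.999, length.out = 41)
    # route 1: dimensional product form
    r1 <- as.numeric(imap_performance(t, p, clamp = FALSE))
    # route 2: asymptotic-population normalisation, written out explicitly
    r2 <- p$scale * exp(p$alpha0 / p$alphar) *
      exp(-(p$alpha0 / p$alphar) * exp(-p$alphar * t)) *
      (1 - exp(p$betar * (t - p$td)))
    # route 3: scale_inf times the dimensionless curve
    r3 <- s$scale_inf * as.numeric(imap_reduced(t / s$td, s, clamp = FALSE))
    expect_equal(r1, r2, tolerance = 1e-12)
    expect_equal(r1, r3, tolerance = 1e-12)
  }
})

test_that("performance is positive before death and unimodal", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_shape()
    p <- redimensionalize(s)
    t <- seq(s$td * 1e-4, s$td * (1 - 1e-6), length.out = 400)
    v <- as.numeric(imap_performance(t, p))
    expect_true(all(v > 0))
    # single sign change of the numerical derivative
    sgn <- sign(diff(v))
    sgn <- sgn[sgn != 0]
    expect_lte(sum(diff(sgn) != 0), 1)
  }
})

test_that("multi-type model matches exponential growth and collapses to one type", {
  # constant rates: P(t) = phi * beta * n0 * e^(alpha t)
  ct <- cell_type(phi = 2, n0 = 100,
                  growth_rate_fn = function(t) rep(0.1, length(t)),
                  senescence_fn = function(t) rep(0.8, length(t)))
  t <- c(0, 1, 2, 5, 10)
  out <- multitype_performance(t, list(ct))
  expect_equal(out$performance, 2 * 0.8 * 100 * exp(0.1 * t),
               tolerance = 1e-8)

  # one type with the declining growth rate and senescent functionality
  # collapses to the closed-form integrative curve
  p <- imap_params(scale = 1, alpha0 = 0.276, alphar = 0.172,
                   betar = 0.0176, td = 124.13)
  ct1 <- cell_type(
    phi = 1, n0 = 1,
    growth_rate_fn = function(t) imap_growth_rate(t, p$alpha0, p$alphar),
    senescence_fn = function(t) imap_senescence(t, 1, p$betar, p$td)
  )
  t <- seq(0, 120, length.out = 25)
  out1 <- multitype_performance(t, list(ct1))
  expect_equal(out1$performance,
               as.numeric(imap_performance(t, p, clamp = FALSE)),
               tolerance = 1e-6)

  # additivity: two identical half-populations equal one full population
  half <- cell_type(
    phi = 1, n0 = 0.5,
    growth_rate_fn = function(t) imap_growth_rate(t, p$alpha0, p$alphar),
    senescence_fn = function(t) imap_senescence(t, 1, p$betar, p$td)
  )
  out2 <- multitype_performance(t, list(half, half))
  expect_equal(out2$performance, out1$performance, tolerance = 1e-12)

  expect_error(multitype_performance(c(2, 1), list(ct)), "sorted")
  expect_error(multitype_performance(t, list()), "non-empty")
})
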