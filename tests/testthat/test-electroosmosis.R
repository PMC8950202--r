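test_that("analytic potential reproduces both wall boundary conditions", {
  g <- dimensionless_geometry(0.5, 0.5)
  for (x in c(0, 0.25)) {
    w <- wall_positions(x, g)
    for (k in c(2, 2.3)) {
      for (z1 in c(1, 1.6)) {
        ek <- electrokinetic_params(kappa = k, zeta1 = z1, zeta2 = 1)
        cf <- potential_coefficients(ek, w$h1, w$h2)
        expect_equal(potential(w$h1, cf, k), z1, tolerance = 1e-12)
        expect_equal(potential(w$h2, cf, k), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("potential satisfies phi'' = kappa^2 * phi (second-difference check)", {
  g <- dimensionless_geometry(0.5, 0.5)
  w <- wall_positions(0, g)
  k <- 2.3
  ek <- electrokinetic_params(kappa = k, zeta1 = 1.6, zeta2 = 1)
  cf <- potential_coefficients(ek, w$h1, w$h2)
  y <- seq(w$h1, w$h2, length.out = 201)
  h <- y[2] - y[1]
  ph <- potential(y, cf, k)
  d2 <- (ph[-c(1, 2)] - 2 * ph[-c(1, 201)] + ph[-c(200, 201)]) / h^2
  # second differences of the analytic solution approach kappa^2*phi at O(h^2)
  expect_lt(max(abs(d2 - k^2 * ph[2:200])), k^4 * max(abs(ph)) * h^2)
  # and the analytic second derivative is exact
  expect_equal(k^2 * ph, k^2 * potential(y, cf, k), tolerance = 1e-12)
})

test_that("symmetric zeta potentials give the even closed-form solution", {
  # zeta1 = zeta2 = 1, h = +/- 1.5, kappa = 2: B = 0, phi(0) = 1/cosh(3)
  ek <- electrokinetic_params(kappa = 2, zeta1 = 1, zeta2 = 1)
  cf <- potential_coefficients(ek, -1.5, 1.5)
  expect_equal(cf$B, 0, tolerance = 1e-15)
  expect_equal(potential(0, cf, 2), 0.099327927419433208, tolerance = 1e-12)
  # antisymmetric case: phi(0) = 0
  eka <- electrokinetic_params(kappa = 2, zeta1 = -1, zeta2 = 1)
  cfa <- potential_coefficients(eka, -1.5, 1.5)
  expect_equal(potential(0, cfa, 2), 0, tolerance = 1e-14)
})

test_that("body force equals U_HS * kappa^2 * phi' (symbolic oracle)", {
  g <- dimensionless_geometry(0.4, 0.6, phi = pi / 4)
  w <- wall_positions(0.15, g)
  k <- 2.1
  ek <- electrokinetic_params(kappa = k, zeta1 = 1.4, zeta2 = 0.8, U_HS = 2.5)
  cf <- potential_coefficients(ek, w$h1, w$h2)
  y <- seq(w$h1, w$h2, length.out = 101)
  # independent symbolic differentiation of the potential expression
  dphi <- stats::D(expression(A * cosh(k * y) - B * sinh(k * y)), "y")
  phip <- eval(dphi, list(A = cf$A, B = cf$B, k = k, y = y))
  expect_lt(max(abs(body_force(y, cf, k, ek$U_HS) - ek$U_HS * k^2 * phip)),
            1e-10)
  # U_HS = 0 kills the force
  expect_identical(body_force(y, cf, k, 0), rep(0, length(y)))
  # symmetric-zeta case vanishes at the channel centre
  cfs <- potential_coefficients(
    electrokinetic_params(kappa = 2, zeta1 = 1, zeta2 = 1), -1.5, 1.5)
  expect_equal(body_force(0, cfs, 2, 3), 0, tolerance = 1e-14)
})

test_that("zero zeta potentials give the zero potential, and A,B otherwise", {
  cf0 <- potential_coefficients(
    electrokinetic_params(kappa = 2, zeta1 = 0, zeta2 = 0), -1.5, 1.5)
  expect_identical(c(cf0$A, cf0$B), c(0, 0))
  expect_identical(potential(seq(-1, 1, 0.5), cf0, 2), rep(0, 5))
})

test_that("relabeling the walls leaves the potential unchanged", {
  k <- 2.2
  ek12 <- electrokinetic_params(kappa = k, zeta1 = 1.3, zeta2 = 0.7)
  cf <- potential_coefficients(ek12, -1.2, 1.4)
  # relabeling (zeta1, h1) <-> (zeta2, h2) in the coefficient formula leaves
  # the potential unchanged
  y <- seq(-1.2, 1.4, length.out = 51)
  A2 <- (1.3 * sinh(k * 1.4) - 0.7 * sinh(k * -1.2)) / sinh(k * (1.4 - -1.2))
  B2 <- (1.3 * cosh(k * 1.4) - 0.7 * cosh(k * -1.2)) / sinh(k * (1.4 - -1.2))
  expect_equal(potential(y, cf, k), A2 * cosh(k * y) - B2 * sinh(k * y),
               tolerance = 1e-12)
})

test_that("large kappa*width is evaluated stably; true overflow errors", {
  ek <- electrokinetic_params(kappa = 40, zeta1 = 1, zeta2 = 1.5)
  cf <- potential_coefficients(ek, -1.5, 1.5)   # kappa*w = 120: scaled form
  expect_true(all(is.finite(c(cf$A, cf$B))))
  expect_equal(potential(-1.5, cf, 40), 1, tolerance = 1e-9)
  expect_equal(potential(1.5, cf, 40), 1.5, tolerance = 1e-9)
  ek2 <- electrokinetic_params(kappa = 600, zeta1 = 1, zeta2 = 1)
  expect_error(potential_coefficients(ek2, -1.5, 1.5), "overflow")
})
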