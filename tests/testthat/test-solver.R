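test_that("trivial limit reproduces the cubic stream function exactly", {
  sol <- solve_station(0, trivial_params(), mix = pure_fluid(),
                       ek = zero_electro())
  ref <- cubic_reference(sol$grid)
  expect_lt(max(abs(sol$states["psi", ] - ref$psi)), 1e-10)
  expect_lt(max(abs(sol$states["dpsi", ] - ref$dpsi)), 1e-10)
  expect_equal(midpoint_state(sol, "dpsi"), 1.0, tolerance = 1e-10)
  # linear scalar fields: midpoint value 1/2, uniform slope 1/3
  for (f in c("theta", "sigma", "chi"))
    expect_equal(midpoint_state(sol, f), 0.5, tolerance = 1e-10)
  expect_equal(max(abs(sol$states["dtheta", ] - 1 / 3)), 0, tolerance = 1e-10)
  expect_lt(sol$bc_residual, 1e-10)
  expect_lt(sol$ode_residual, 1e-8)
})

test_that("solver matches the closed-form linear momentum solution", {
  mix0 <- pure_fluid()
  # non-resonant: M = 3, kappa = 2
  p <- model_parameters(Gr = 0, M = 3, Nt = 0, Nb = 0, xi = 0, Pe = 0)
  sol <- solve_station(0, p, mix = mix0)
  cfm <- closed_form_momentum(p, mix0)
  y <- sol$grid
  err <- max(abs(sol$states["psi", ] - cfm$psi(y)),
             abs(sol$states["dpsi", ] - cfm$dpsi(y)),
             abs(sol$states["d2psi", ] - cfm$d2psi(y)),
             abs(sol$states["d3psi", ] - cfm$d3psi(y)))
  expect_lt(err, 1e-6)
  # the analytic solution satisfies the momentum ODE pointwise
  resid <- mix0$mu_r * cfm$d4psi(y) - mix0$sigma_r * p$M^2 * cfm$d2psi(y) +
    body_force(y, sol$coeffs, 2, 1)
  expect_lt(max(abs(resid)), 1e-9)
  # M > 0 with U_HS = 0: hyperbolic basis only, still solved exactly
  pM <- model_parameters(Gr = 0, M = 2, Nt = 0, Nb = 0, xi = 0, Pe = 0)
  cf0 <- closed_form_momentum(pM, mix0, zero_electro())
  s0 <- solve_station(0, pM, mix = mix0, ek = zero_electro())
  expect_lt(max(abs(s0$states["psi", ] - cf0$psi(s0$grid))), 1e-8)
})

test_that("resonant forcing (kappa equal to the Hartmann wavenumber) is handled", {
  p <- model_parameters(Gr = 0, M = 2, Nt = 0, Nb = 0, xi = 0, Pe = 0)
  mix0 <- pure_fluid()
  cfm <- closed_form_momentum(p, mix0, electrokinetic_params(kappa = 2, U_HS = 1))
  y <- seq(-1.5, 1.5, length.out = 201)
  w <- wall_positions(0, dimensionless_geometry())
  cf <- potential_coefficients(electrokinetic_params(kappa = 2), w$h1, w$h2)
  resid <- cfm$d4psi(y) - 4 * cfm$d2psi(y) + body_force(y, cf, 2, 1)
  expect_lt(max(abs(resid)), 1e-9)
  sol <- solve_station(0, p, mix = mix0)
  expect_lt(max(abs(sol$states["psi", ] - cfm$psi(sol$grid))), 1e-6)
})

test_that("closed form refuses buoyant problems", {
  expect_error(closed_form_momentum(model_parameters(Gr = 1)), "Gr = 0")
})

test_that("stream function is odd in the symmetric buoyancy-free configuration", {
  sol <- solve_station(0, model_parameters(Gr = 0))
  y <- seq(0, sol$h2, length.out = 101)
  odd <- max(abs(predict(sol, y)["psi", ] + predict(sol, -y)["psi", ]))
  expect_lt(odd, 1e-8)
})

test_that("all ten boundary rows hold to 1e-10 on converged solutions", {
  for (sol in list(solve_station(),
                   solve_station(0.25, model_parameters(M = 4, Gr = 3)),
                   fd_oracle_solve(n = 401))) {
    expect_lt(sol$bc_residual, 1e-10)
    expect_equal(unname(sol$states["dpsi", 1]), -1, tolerance = 1e-10)
    expect_equal(unname(sol$states["dpsi", ncol(sol$states)]), -1,
                 tolerance = 1e-10)
    expect_equal(unname(sol$states["psi", ncol(sol$states)] -
                          sol$states["psi", 1]),
                 sol$params$F, tolerance = 1e-10)
  }
})

test_that("collocation and finite-difference solvers agree at defaults", {
  sol <- solve_station()
  fo <- fd_oracle_solve()
  expect_lt(max(abs(predict(sol, fo$grid) - fo$states)), 1e-4)
})

test_that("the finite-difference oracle converges at second order", {
  sol <- solve_station()     # reference: fourth-order collocation, refined mesh
  e <- vapply(c(401, 801), function(n) {
    fo <- fd_oracle_solve(n = n)
    max(abs(predict(sol, fo$grid) - fo$states))
  }, numeric(1))
  expect_gt(e[1] / e[2], 2.5)
  expect_lt(e[1] / e[2], 6)
})

test_that("the FD oracle is exact for the trivial cubic up to truncation", {
  fo <- fd_oracle_solve(0, trivial_params(), mix = pure_fluid(),
                        ek = zero_electro(), n = 801)
  ref <- cubic_reference(fo$grid)
  expect_lt(max(abs(fo$states["psi", ] - ref$psi)), 1e-5)
  expect_lt(max(abs(fo$states["dpsi", ] - ref$dpsi)), 1e-5)
})

test_that("profiles are mesh-independent beyond the residual tolerance", {
  s1 <- solve_station(opts = solver_options(n_init = 101))
  s2 <- solve_station(opts = solver_options(n_init = 201))
  y <- seq(s1$h1, s1$h2, length.out = 101)
  expect_lt(max(abs(predict(s1, y) - predict(s2, y))), 1e-7)
})

test_that("solver options validate and the continuation path is recorded", {
  expect_error(solver_options(tol = 0), "positive")
  expect_error(solver_options(n_init = 5), "at least 11")
  # a hard nonlinear case exercises the continuation ramp without failing
  sol <- suppressWarnings(
    solve_station(p = model_parameters(Nt = 9),
                  opts = solver_options(max_nodes = 801)))
  expect_s3_class(sol, "station_solution")
})
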