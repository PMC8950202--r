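test_that("shear stress matches the closed-form cubic and viscosity scaling", {
  sol <- solve_station(0, trivial_params(), mix = pure_fluid(),
                       ek = zero_electro())
  # tau_s = mu_r * psi''(h1) = 3*(F + 2h)/(2h^2) = 8/3 for F = 1, h = 1.5
  expect_equal(shear_stress(sol), 8 / 3, tolerance = 1e-8)
  mix5 <- mixture_properties(0.05, particle_shape("bricks"))
  sol5 <- solve_station(0, trivial_params(), mix = mix5, ek = zero_electro())
  expect_equal(shear_stress(sol5), 8 / 3 * 2.2735, tolerance = 1e-7)
  expect_equal(shear_stress(sol5), 6.0627, tolerance = 1e-4)
  # zero net wave-frame pumping: psi has no curvature, stress vanishes
  h <- 1.5
  solz <- solve_station(0, trivial_params(F = -2 * h), mix = pure_fluid(),
                        ek = zero_electro())
  expect_equal(shear_stress(solz), 0, tolerance = 1e-9)
  # symmetric configuration: right-wall variant mirrors the left
  expect_equal(shear_stress(sol, wall = "right"), -shear_stress(sol),
               tolerance = 1e-8)
})

test_that("velocity profiles respect the frame transformation and no-slip", {
  sol <- solve_station()
  vp <- velocity_profiles(sol)
  expect_equal(vp$u_lab, vp$u_wave + 1)
  n <- nrow(vp)
  expect_equal(vp$u_wave[c(1, n)], c(-1, -1), tolerance = 1e-10)
  expect_equal(vp$u_lab[c(1, n)], c(0, 0), tolerance = 1e-10)
  # trivial cubic centre velocity: parabola 1 - (8/9) y^2 for F = 1, h = 1.5
  st <- solve_station(0, trivial_params(), mix = pure_fluid(),
                      ek = zero_electro())
  vt <- velocity_profiles(st)
  expect_equal(vt$u_wave, 1 - (8 / 9) * vt$y^2, tolerance = 1e-9)
})

test_that("heat-flux diagnostic follows its linear-limit closed form", {
  p0 <- model_parameters(M = 0, Gr = 0, Nb = 0, Nt = 0, xi = 0, Pe = 0,
                         Rn = 0, F = 1)
  sol <- solve_station(0, p0, mix = pure_fluid(), ek = zero_electro())
  # theta' = 1/(h2 - h1) = 1/3, Rn = 0, k_r = 1: Nu = -1/3
  expect_equal(heat_flux_diagnostic(sol), -1 / 3, tolerance = 1e-9)
  # coefficient scaling: Rn*Pr = 1 doubles it
  p1 <- model_parameters(M = 0, Gr = 0, Nb = 0, Nt = 0, xi = 0, Pe = 0,
                         Rn = 0.5, Pr = 2, F = 1)
  sol1 <- solve_station(0, p1, mix = pure_fluid(), ek = zero_electro())
  expect_equal(heat_flux_diagnostic(sol1), -2 / 3, tolerance = 1e-9)
})

test_that("parameter sweeps produce tidy tables and propagate identity", {
  tab <- parameter_sweep("M", c(0, 2), xs = 0,
                         opts = solver_options(n_init = 51, tol = 1e-6))
  expect_setequal(unique(tab$field),
                  c("psi", "u_wave", "u_lab", "theta", "sigma", "chi"))
  expect_setequal(unique(tab$value), c(0, 2))
  sc <- attr(tab, "scalars")
  expect_equal(nrow(sc), 2)
  expect_true(all(c("tau_s", "Nu") %in% names(sc)))
  # empty sweep: empty table
  empty <- parameter_sweep("M", numeric(0))
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(attr(empty, "scalars")), 0)
  # unknown parameter is rejected
  expect_error(parameter_sweep("bogus", 1), "unknown sweep parameter")
})

test_that("shape sweeps re-mix the nanofluid", {
  tab <- parameter_sweep("shape", c("bricks", "platelets"), xs = 0,
                         opts = solver_options(n_init = 51, tol = 1e-6))
  expect_setequal(unique(tab$value), c("bricks", "platelets"))
  sc <- attr(tab, "scalars")
  expect_equal(nrow(sc), 2)
  expect_false(sc$tau_s[1] == sc$tau_s[2])
})

test_that("shear stress is 1-periodic in x and inherits wall symmetry", {
  p <- model_parameters(Gr = 0)
  tau_at <- function(x) shear_stress(
    solve_station(x, p, opts = solver_options(n_init = 51, tol = 1e-6)))
  expect_equal(tau_at(0.2), tau_at(1.2), tolerance = 1e-6)
})
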