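#' Thermophysical properties of a fluid or particle material
#'
#' @param rho Density (kg/m^3).
#' @param cp Specific heat (J/(kg K)).
#' @param k Thermal conductivity (W/(m K)).
#' @param sigma Electrical conductivity (S/m).
#' @param beta Thermal expansion coefficient (1/K).
#' @param mu Dynamic viscosity (kg/(m s)); base fluid only, `NA` for solids.
#'
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho, cp, k, sigma, beta, mu = NA_real_) {
  vals <- c(rho = rho, cp = cp, k = k, sigma = sigma, beta = beta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all material properties must be finite and positive", call. = FALSE)
  if (!is.na(mu) && mu <= 0)
    stop("viscosity `mu` must be positive when given", call. = FALSE)
  structure(list(rho = rho, cp = cp, k = k, sigma = sigma, beta = beta, mu = mu),
            class = "fluid_properties")
}

#' Built-in material constants: gold nanoparticles
#'
#' k = 314 W/(m K), cp = 129 J/(kg K), rho = 19320 kg/m^3,
#' sigma = 4.52e7 S/m, beta = 1.4e-5 1/K.
#'
#' @return A [fluid_properties()] record for gold.
#' @export
gold_properties <- function() {
  fluid_properties(rho = 19320, cp = 129, k = 314, sigma = 4.52e7, beta = 1.4e-5)
}

#' Built-in material constants: blood (base fluid)
#'
#' k = 0.492 W/(m K), cp = 3594 J/(kg K), rho = 1063 kg/m^3,
#' sigma = 0.667 S/m, beta = 0.18e-5 1/K, mu = 4e-4 kg/(m s).
#'
#' The viscosity is used only by the dimensional converter
#' ([nondimensionalize()]); the dimensionless core never derives groups from
#' it.
#'
#' @return A [fluid_properties()] record for blood.
#' @export
blood_properties <- function() {
  fluid_properties(rho = 1063, cp = 3594, k = 0.492, sigma = 0.667,
                   beta = 0.18e-5, mu = 4e-4)
}

.shape_registry <- list(
  bricks    = list(s = 3.72, A1 = 1.9,  A2 = 471.4),
  platelets = list(s = 5.72, A1 = 37.1, A2 = 612.6),
  cylinders = list(s = 4.82, A1 = 13.5, A2 = 904.4)
)

#' Nanoparticle shape descriptor
#'
#' Shape factor `s` enters the Hamilton--Crosser-type conductivity model;
#' `A1`, `A2` are the linear and quadratic viscosity coefficients of the
#' particle-laden mixture. Registry values: bricks (s = 3.72, A1 = 1.9,
#' A2 = 471.4), platelets (s = 5.72, A1 = 37.1, A2 = 612.6), cylinders
#' (s = 4.82, A1 = 13.5, A2 = 904.4). A user-defined shape is accepted via
#' `name = "custom"` together with explicit `s`, `A1`, `A2`.
#'
#' @param name One of `"bricks"`, `"platelets"`, `"cylinders"`, `"custom"`.
#' @param s,A1,A2 Shape factor and viscosity coefficients; required (and only
#'   honoured) for `name = "custom"`.
#' @return An object of class `particle_shape`.
#' @export
#' @examples
#' particle_shape("platelets")
#' particle_shape("custom", s = 3, A1 = 2.5, A2 = 6.2)
particle_shape <- function(name = c("bricks", "platelets", "cylinders", "custom"),
                           s = NULL, A1 = NULL, A2 = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(s) || is.null(A1) || is.null(A2))
      stop("custom shapes require `s`, `A1` and `A2`", call. = FALSE)
  } else {
    if (!is.null(s) || !is.null(A1) || !is.null(A2))
      stop("registry shapes fix `s`, `A1`, `A2`; use name = \"custom\" to override",
           call. = FALSE)
    reg <- .shape_registry[[name]]
    s <- reg$s; A1 <- reg$A1; A2 <- reg$A2
  }
  if (s <= 0) stop("shape factor `s` must be positive", call. = FALSE)
  if (A1 < 0 || A2 < 0)
    stop("viscosity coefficients `A1`, `A2` must be non-negative", call. = FALSE)
  structure(list(name = name, s = s, A1 = A1, A2 = A2), class = "particle_shape")
}

#' Effective mixture-property ratios of the nanofluid
#'
#' Computes the six dimensionless effective-property ratios of the
#' particle/base-fluid mixture at particle volume fraction `phi1`:
#'
#' * `mu_r  = 1 + A1*phi1 + A2*phi1^2` (shape-dependent viscosity),
#' * `k_r` from the Hamilton--Crosser-type model with shape factor `s`,
#' * `sigma_r = 1 + 3*(r - 1)*phi1 / ((r + 2) - (r - 1)*phi1)`,
#'   `r = sigma_p/sigma_f` (Maxwell-type conductivity),
#' * `rho_r`, `rhobeta_r`, `rhocp_r`: volume-fraction-weighted mixture rules.
#'
#' All six ratios are exactly 1 at `phi1 = 0`. `mu_r`, `sigma_r`,
#' `rhobeta_r` and `k_r` are the coefficients multiplying the viscous,
#' Lorentz, thermal-buoyancy and conduction terms of the reduced governing
#' system; `rhocp_r` also yields the heat-capacity ratio
#' `tau = (rho*cp)_p/(rho*cp)_f` used by the dimensional converter.
#'
#' @param phi1 Particle volume fraction, in `[0, 1)`.
#' @param shape A [particle_shape()] (or a shape name).
#' @param base,particle [fluid_properties()] of the base fluid and particles;
#'   default blood and gold.
#'
#' @return An object of class `mixture_ratios` with fields `mu_r`, `k_r`,
#'   `sigma_r`, `rho_r`, `rhobeta_r`, `rhocp_r`, `tau`, plus the `phi1` and
#'   shape used.
#' @export
#' @examples
#' mixture_properties(0.05, particle_shape("bricks"))
mixture_properties <- function(phi1, shape = particle_shape("bricks"),
                               base = blood_properties(),
                               particle = gold_properties()) {
  if (is.character(shape)) shape <- particle_shape(shape)
  stopifnot(inherits(shape, "particle_shape"),
            inherits(base, "fluid_properties"),
            inherits(particle, "fluid_properties"))
  if (!is.numeric(phi1) || length(phi1) != 1L || !is.finite(phi1) ||
      phi1 < 0 || phi1 >= 1)
    stop("particle volume fraction `phi1` must lie in [0, 1)", call. = FALSE)

  s <- shape$s
  mu_r <- 1 + shape$A1 * phi1 + shape$A2 * phi1^2
  kp <- particle$k; kf <- base$k
  k_r <- (kp + (s - 1) * kf - (s - 1) * phi1 * (kf - kp)) /
         (kp + (s - 1) * kf + phi1 * (kf - kp))
  r <- particle$sigma / base$sigma
  sigma_r <- 1 + 3 * (r - 1) * phi1 / ((r + 2) - (r - 1) * phi1)
  rho_r <- (1 - phi1) + phi1 * particle$rho / base$rho
  rhobeta_r <- (1 - phi1) +
    phi1 * (particle$rho * particle$beta) / (base$rho * base$beta)
  tau <- (particle$rho * particle$cp) / (base$rho * base$cp)
  rhocp_r <- (1 - phi1) + phi1 * tau

  structure(list(mu_r = mu_r, k_r = k_r, sigma_r = sigma_r, rho_r = rho_r,
                 rhobeta_r = rhobeta_r, rhocp_r = rhocp_r, tau = tau,
                 phi1 = phi1, shape = shape),
            class = "mixture_ratios")
}

#' @export
print.mixture_ratios <- function(x, ...) {
  cat(sprintf("Nanofluid mixture ratios (phi1 = %g, shape = %s):\n",
              x$phi1, x$shape$name))
  cat(sprintf("  mu_r = %.6g  k_r = %.6g  sigma_r = %.6g\n",
              x$mu_r, x$k_r, x$sigma_r))
  cat(sprintf("  rho_r = %.6g  rhobeta_r = %.6g  rhocp_r = %.6g\n",
              x$rho_r, x$rhobeta_r, x$rhocp_r))
  invisible(x)
}

#' @export
print.particle_shape <- function(x, ...) {
  cat(sprintf("Particle shape '%s': s = %g, A1 = %g, A2 = %g\n",
              x$name, x$s, x$A1, x$A2))
  invisible(x)
}
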