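#' Dimensionless model parameters
#'
#' All dimensionless groups of the reduced governing system in one validated
#' record. Defaults are mid-range values of the ranges the underlying model is
#' exercised over (see the methods vignette); they are a package convention
#' wherever the literature states only a range.
#'
#' @param M Hartmann number (magnetic/viscous force ratio), `>= 0`.
#' @param Gr Thermal Grashof number, `>= 0`.
#' @param Nr Buoyancy ratio (nanoparticle vs thermal stratification).
#' @param Rb Bioconvection Rayleigh number.
#' @param Rn Radiation parameter, `>= 0`.
#' @param Pr Prandtl number, `>= 0`.
#' @param Nb Brownian-motion parameter, `>= 0`. `Nb = 0` is allowed only
#'   together with `Nt = 0` (the thermophoresis/Brownian ratio then drops out).
#' @param Nt Thermophoresis parameter, `>= 0`.
#' @param Sc Schmidt number, `>= 0`.
#' @param xi Reaction-rate constant, `>= 0`.
#' @param beta_t Temperature-ratio parameter of the Arrhenius term, `>= 0`.
#' @param E Activation-energy parameter, `>= 0`.
#' @param n_fit Fitted rate exponent, in `(-1, 1)`.
#' @param Pe Bioconvection Peclet number, `>= 0`.
#' @param Omega Microorganism concentration-difference constant.
#' @param F Wave-frame flow rate. The default 1 corresponds to a fixed-frame
#'   mean flow rate `Q = 3.5` at the reference geometry `a = b = 0.5`
#'   (see [flow_rate_relation()]).
#'
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(M = 2, Gr = 2, Nr = 1, Rb = 1, Rn = 0.4, Pr = 21,
                             Nb = 0.5, Nt = 1, Sc = 1, xi = 1, beta_t = 1,
                             E = 1, n_fit = 0.5, Pe = 0.5, Omega = 1, F = 1) {
  p <- list(M = M, Gr = Gr, Nr = Nr, Rb = Rb, Rn = Rn, Pr = Pr, Nb = Nb,
            Nt = Nt, Sc = Sc, xi = xi, beta_t = beta_t, E = E, n_fit = n_fit,
            Pe = Pe, Omega = Omega, F = F)
  if (any(!vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1))))
    stop("all model parameters must be finite scalars", call. = FALSE)
  nonneg <- c("M", "Gr", "Rn", "Pr", "Nb", "Nt", "Sc", "xi", "beta_t", "E", "Pe")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad))
    stop("parameters must be non-negative: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (n_fit <= -1 || n_fit >= 1)
    stop("fitted rate exponent `n_fit` must lie in (-1, 1)", call. = FALSE)
  if (Nb == 0 && Nt != 0)
    stop("`Nb = 0` is only permitted when `Nt = 0`", call. = FALSE)
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Dimensionless model parameters:\n")
  nm <- names(unclass(x))
  vals <- vapply(unclass(x), function(v) sprintf("%g", v), character(1))
  cat(paste0("  ", format(nm, width = 7), "= ", vals, collapse = "\n"), "\n")
  invisible(x)
}

# Modified-Arrhenius reaction factor (1 + beta*theta)^n * exp(-E/(1 + beta*theta))
# and its theta-derivative. The evaluation domain is clamped at
# 1 + beta*theta >= floor (derivative zeroed where the clamp is active);
# with clamp = FALSE a non-positive denominator is a domain error.
.reaction_factor <- function(theta, p, clamp = TRUE, floor = 1e-8) {
  tp <- 1 + p$beta_t * theta
  if (!clamp && any(tp <= 0))
    stop("activation-energy denominator 1 + beta_t*theta is non-positive",
         call. = FALSE)
  clamped <- tp < floor
  tp <- pmax(tp, floor)
  g <- tp^p$n_fit * exp(-p$E / tp)
  dg <- g * p$beta_t * (p$n_fit / tp + p$E / tp^2)
  dg[clamped] <- 0
  list(g = g, dg = dg)
}

#' Right-hand side of the ten-state first-order system
#'
#' The reduced governing equations written as `d(state)/dy = f(y, state)` with
#' state `(psi, psi', psi'', psi''', theta, theta', sigma, sigma', chi, chi')`:
#'
#' * momentum: `y4' = (a2*M^2*y3 - Gr*(a3*y6 - Nr*y8 - Rb*y10) - bf(y)) / a1`,
#'   where `a1 = mu_r`, `a2 = sigma_r`, `a3 = rhobeta_r` and `bf` is
#'   [body_force()];
#' * energy: `y6' = -Pr*(Nb*y6*y8 + Nt*y6^2) / (a4 + Rn*Pr)`, `a4 = k_r`;
#' * concentration: `y8' = -(Nt/Nb)*y6' + Sc*xi*y7*(1+beta_t*y5)^n*exp(-E/(1+beta_t*y5))`;
#' * microorganisms: `y10' = Pe*(y9 + Omega)*y8' + Pe*y8*y10`.
#'
#' @param y Transverse position(s); length `n`.
#' @param state Numeric state: a length-10 vector, or a `10 x n` matrix with
#'   one column per position.
#' @param p A [model_parameters()].
#' @param mix A [mixture_ratios()][mixture_properties()].
#' @param ek An [electrokinetic_params()].
#' @param coeffs A [potential_coefficients()] for the wall pair at the current
#'   axial station.
#' @param clamp Clamp the Arrhenius denominator at `1e-8` (solver behaviour)
#'   instead of raising a domain error. Default `FALSE` for direct calls.
#'
#' @return Derivatives with the same shape as `state`.
#' @export
ode_rhs <- function(y, state, p, mix, ek, coeffs, clamp = FALSE) {
  stopifnot(inherits(p, "model_parameters"), inherits(mix, "mixture_ratios"),
            inherits(ek, "electrokinetic_params"),
            inherits(coeffs, "potential_coefficients"))
  vec <- is.null(dim(state))
  Y <- if (vec) matrix(state, nrow = 10L) else state
  if (nrow(Y) != 10L) stop("`state` must have 10 rows", call. = FALSE)
  FY <- .rhs_eval(y, Y, p, mix, ek, coeffs, clamp = clamp)
  if (vec) drop(FY) else FY
}

.rhs_eval <- function(y, Y, p, mix, ek, coeffs, clamp = TRUE) {
  a1 <- mix$mu_r; a2 <- mix$sigma_r; a3 <- mix$rhobeta_r; a4 <- mix$k_r
  D <- a4 + p$Rn * p$Pr
  bf <- body_force(y, coeffs, ek$kappa, ek$U_HS)
  F4 <- (a2 * p$M^2 * Y[3L, ] -
           p$Gr * (a3 * Y[6L, ] - p$Nr * Y[8L, ] - p$Rb * Y[10L, ]) - bf) / a1
  F6 <- -(p$Pr / D) * (p$Nb * Y[6L, ] * Y[8L, ] + p$Nt * Y[6L, ]^2)
  r <- if (p$Nb > 0) p$Nt / p$Nb else 0
  rf <- .reaction_factor(Y[5L, ], p, clamp = clamp)
  F8 <- -r * F6 + p$Sc * p$xi * Y[7L, ] * rf$g
  F10 <- p$Pe * (Y[9L, ] + p$Omega) * F8 + p$Pe * Y[8L, ] * Y[10L, ]
  rbind(Y[2L, ], Y[3L, ], Y[4L, ], F4,
        Y[6L, ], F6, Y[8L, ], F8, Y[10L, ], F10, deparse.level = 0L)
}

# Jacobian d f / d state of .rhs_eval: 10 x 10 x n array.
.rhs_jacobian <- function(y, Y, p, mix, ek, coeffs) {
  n <- ncol(Y)
  a1 <- mix$mu_r; a2 <- mix$sigma_r; a3 <- mix$rhobeta_r; a4 <- mix$k_r
  D <- a4 + p$Rn * p$Pr
  J <- array(0, dim = c(10L, 10L, n))
  J[1L, 2L, ] <- 1; J[2L, 3L, ] <- 1; J[3L, 4L, ] <- 1
  J[4L, 3L, ] <- a2 * p$M^2 / a1
  J[4L, 6L, ] <- -p$Gr * a3 / a1
  J[4L, 8L, ] <- p$Gr * p$Nr / a1
  J[4L, 10L, ] <- p$Gr * p$Rb / a1
  J[5L, 6L, ] <- 1
  J[6L, 6L, ] <- -(p$Pr / D) * (p$Nb * Y[8L, ] + 2 * p$Nt * Y[6L, ])
  J[6L, 8L, ] <- -(p$Pr / D) * p$Nb * Y[6L, ]
  J[7L, 8L, ] <- 1
  r <- if (p$Nb > 0) p$Nt / p$Nb else 0
  rf <- .reaction_factor(Y[5L, ], p, clamp = TRUE)
  J[8L, 5L, ] <- p$Sc * p$xi * Y[7L, ] * rf$dg
  J[8L, 6L, ] <- -r * J[6L, 6L, ]
  J[8L, 7L, ] <- p$Sc * p$xi * rf$g
  J[8L, 8L, ] <- -r * J[6L, 8L, ]
  J[9L, 10L, ] <- 1
  F6 <- -(p$Pr / D) * (p$Nb * Y[6L, ] * Y[8L, ] + p$Nt * Y[6L, ]^2)
  F8 <- -r * F6 + p$Sc * p$xi * Y[7L, ] * rf$g
  fac <- p$Pe * (Y[9L, ] + p$Omega)
  J[10L, 5L, ] <- fac * J[8L, 5L, ]
  J[10L, 6L, ] <- fac * J[8L, 6L, ]
  J[10L, 7L, ] <- fac * J[8L, 7L, ]
  J[10L, 8L, ] <- fac * J[8L, 8L, ] + p$Pe * Y[10L, ]
  J[10L, 9L, ] <- p$Pe * F8
  J[10L, 10L, ] <- p$Pe * Y[8L, ]
  J
}

#' Boundary-condition residuals of the two-point problem
#'
#' The ten boundary rows: at the left wall `psi = -F/2`, `psi' = -1`,
#' `theta = sigma = chi = 0`; at the right wall `psi = F/2`, `psi' = -1`,
#' `theta = sigma = chi = 1`.
#'
#' @param state_h1 Length-10 state at the left wall `y = h1`.
#' @param state_h2 Length-10 state at the right wall `y = h2`.
#' @param p A [model_parameters()] (supplies `F`).
#' @return Numeric vector of 10 residuals (zero iff all conditions hold), in
#'   the order left `(psi, psi', theta, sigma, chi)` then right the same.
#' @export
boundary_residual <- function(state_h1, state_h2, p) {
  stopifnot(length(state_h1) == 10L, length(state_h2) == 10L,
            inherits(p, "model_parameters"))
  c(state_h1[1L] + p$F / 2,
    state_h1[2L] + 1,
    state_h1[5L],
    state_h1[7L],
    state_h1[9L],
    state_h2[1L] - p$F / 2,
    state_h2[2L] + 1,
    state_h2[5L] - 1,
    state_h2[7L] - 1,
    state_h2[9L] - 1)
}

#' Physical (dimensional) problem inputs
#'
#' Collects the dimensional quantities consumed by [nondimensionalize()].
#' Temperatures in K, diffusivities in m^2/s, `B0` in T, `Ex` in V/m,
#' `g` in m/s^2, `kr` such that `kr^2` is a reaction rate (1/s), `Ea` and
#' `omega_B` in consistent energy/temperature units (the default `omega_B`
#' is the Boltzmann constant in eV/K, so `Ea` is then in eV).
#'
#' @param B0 Magnetic flux density (T).
#' @param g Gravity (m/s^2).
#' @param T0,T1 Left/right wall temperatures (K), `T1 >= T0 > 0`.
#' @param C0,C1 Wall nanoparticle concentrations.
#' @param N0,N1 Wall motile-organism densities.
#' @param DB,DT,Dm Brownian, thermophoretic and microorganism diffusivities
#'   (m^2/s), `> 0`.
#' @param Tm Mean temperature (K).
#' @param kr Reaction-rate constant (`kr^2` in 1/s).
#' @param Ea Activation energy (units matching `omega_B`).
#' @param omega_B Boltzmann constant (default 8.61e-5 eV/K).
#' @param sigma_star Stefan--Boltzmann constant (W/(m^2 K^4)).
#' @param k_star Mean absorption coefficient (1/m).
#' @param b_chem Chemotaxis constant.
#' @param We Microorganism swimming speed.
#' @param gamma_v Microorganism volume.
#' @param rho_m Motile-organism density (kg/m^3).
#' @param Ex Applied axial electric field (V/m); carried as metadata only
#'   (the Helmholtz--Smoluchowski velocity is a direct dimensionless input,
#'   see [electrokinetic_params()]).
#'
#' @return An object of class `physical_inputs`.
#' @export
physical_inputs <- function(B0, g = 9.81, T0, T1, C0, C1, N0, N1,
                            DB, DT, Dm, Tm = (T0 + T1) / 2, kr, Ea,
                            omega_B = 8.61e-5, sigma_star = 5.67e-8,
                            k_star, b_chem, We, gamma_v, rho_m,
                            Ex = NA_real_) {
  if (T0 <= 0 || T1 < T0)
    stop("wall temperatures must satisfy T1 >= T0 > 0", call. = FALSE)
  if (any(c(DB, DT, Dm) <= 0))
    stop("diffusivities must be positive", call. = FALSE)
  structure(list(B0 = B0, g = g, T0 = T0, T1 = T1, C0 = C0, C1 = C1,
                 N0 = N0, N1 = N1, DB = DB, DT = DT, Dm = Dm, Tm = Tm,
                 kr = kr, Ea = Ea, omega_B = omega_B,
                 sigma_star = sigma_star, k_star = k_star, b_chem = b_chem,
                 We = We, gamma_v = gamma_v, rho_m = rho_m, Ex = Ex),
            class = "physical_inputs")
}

#' Convert dimensional inputs to the dimensionless groups
#'
#' Standard-form conversions: `M = B0*d*sqrt(sigma_f/mu_f)`,
#' `Gr = g*(rho*beta)_f*(1-C0)*(T1-T0)*d^2/(c*mu_f)`,
#' `Nr = (rho_p-rho_f)*(C1-C0) / ((rho*beta)_f*(1-C0)*(T1-T0))`,
#' `Rb = gamma_v*(rho_m-rho_f)*(N1-N0) / ((rho*beta)_f*(1-C0)*(T1-T0))`,
#' `Rn = 16*sigma_star*T0^3/(3*k_star*mu_f*cp_f)`, `Pr = mu_f*cp_f/k_f`,
#' `beta_t = (T1-T0)/T0`, `E = Ea/(omega_B*T0)`,
#' `Nb = tau*DB*(C1-C0)*rho_f/mu_f`, `Nt = tau*DT*(T1-T0)*rho_f/(mu_f*Tm)`
#' with `tau = (rho*cp)_p/(rho*cp)_f`, `Sc = mu_f/(rho_f*DB)`,
#' `xi = kr^2*d^2*rho_f/mu_f`, `Pe = b_chem*We/Dm`, `Omega = N0/(N1-N0)`.
#' The Reynolds number `Re = rho_f*c*d/mu_f` and wave number
#' `delta = d/lambda` are returned as metadata: the lubrication-limit core
#' never uses them. The electroosmotic parameter `kappa` and `U_HS` are
#' *not* derived here; they are direct dimensionless inputs.
#'
#' Degenerate limits: `T1 = T0` yields `beta_t = Gr = Nt = 0` (not an error);
#' `N1 = N0` leaves `Omega` undefined and is an error.
#'
#' @param ph A [physical_inputs()].
#' @param ch A [dimensional_channel()].
#' @param base,particle [fluid_properties()]; `base` must carry a viscosity.
#' @param ... Overrides forwarded to [model_parameters()] (e.g. `F`, or any
#'   group the caller fixes directly).
#'
#' @return A list with components `params` (a [model_parameters()]),
#'   `Re`, `delta` and `tau`.
#' @export
nondimensionalize <- function(ph, ch, base = blood_properties(),
                              particle = gold_properties(), ...) {
  stopifnot(inherits(ph, "physical_inputs"), inherits(ch, "dimensional_channel"))
  muf <- base$mu
  if (is.na(muf)) stop("base fluid must carry a viscosity `mu`", call. = FALSE)
  if (ph$N1 == ph$N0)
    stop("N1 = N0: microorganism concentration-difference constant Omega ",
         "is undefined", call. = FALSE)
  rbf <- base$rho * base$beta
  dT <- ph$T1 - ph$T0
  tau <- (particle$rho * particle$cp) / (base$rho * base$cp)
  buoy <- rbf * (1 - ph$C0) * dT            # shared buoyancy denominator
  groups <- list(
    M = ph$B0 * ch$d * sqrt(base$sigma / muf),
    Gr = if (dT == 0) 0 else ph$g * buoy * ch$d^2 / (ch$c * muf),
    Nr = if (dT == 0) 0 else
      (particle$rho - base$rho) * (ph$C1 - ph$C0) / buoy,
    Rb = if (dT == 0) 0 else
      ph$gamma_v * (ph$rho_m - base$rho) * (ph$N1 - ph$N0) / buoy,
    Rn = 16 * ph$sigma_star * ph$T0^3 / (3 * ph$k_star * muf * base$cp),
    Pr = muf * base$cp / base$k,
    Nb = tau * ph$DB * (ph$C1 - ph$C0) * base$rho / muf,
    Nt = if (dT == 0) 0 else tau * ph$DT * dT * base$rho / (muf * ph$Tm),
    Sc = muf / (base$rho * ph$DB),
    xi = ph$kr^2 * ch$d^2 * base$rho / muf,
    beta_t = dT / ph$T0,
    E = ph$Ea / (ph$omega_B * ph$T0),
    Pe = ph$b_chem * ph$We / ph$Dm,
    Omega = ph$N0 / (ph$N1 - ph$N0))
  groups <- utils::modifyList(groups, list(...))
  list(params = do.call(model_parameters, groups),
       Re = base$rho * ch$c * ch$d / muf,
       delta = ch$d / ch$lambda,
       tau = tau)
}
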