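#' Electrokinetic parameters of the electric double layer
#'
#' @param kappa Electroosmotic parameter (channel half-width over Debye
#'   length), `> 0`.
#' @param zeta1 Dimensionless zeta potential of the left wall.
#' @param zeta2 Dimensionless zeta potential of the right wall. The default
#'   1.0 is a package convention (only the left-wall potential is ranged in
#'   the literature this model targets).
#' @param U_HS Helmholtz--Smoluchowski velocity (signed, dimensionless).
#'
#' @return An object of class `electrokinetic_params`.
#' @export
electrokinetic_params <- function(kappa = 2, zeta1 = 1, zeta2 = 1, U_HS = 1) {
  vals <- c(kappa = kappa, zeta1 = zeta1, zeta2 = zeta2, U_HS = U_HS)
  if (any(!is.finite(vals)))
    stop("electrokinetic parameters must be finite", call. = FALSE)
  if (kappa <= 0) stop("electroosmotic parameter `kappa` must be positive",
                       call. = FALSE)
  structure(as.list(vals), class = "electrokinetic_params")
}

# sinh(x)/sinh(y) without overflow: factor out exp(|x| - |y|).
.sinh_ratio <- function(x, y) {
  sign(x) * sign(y) * exp(abs(x) - abs(y)) *
    (1 - exp(-2 * abs(x))) / (1 - exp(-2 * abs(y)))
}

# cosh(x)/sinh(y), same scaling.
.cosh_sinh_ratio <- function(x, y) {
  sign(y) * exp(abs(x) - abs(y)) *
    (1 + exp(-2 * abs(x))) / (1 - exp(-2 * abs(y)))
}

#' Coefficients of the analytic double-layer potential
#'
#' Under Debye--Hueckel linearisation the transverse potential obeys
#' `phi'' = kappa^2 * phi` with `phi(h1) = zeta1`, `phi(h2) = zeta2`.
#' The solution is `phi(y) = A*cosh(kappa*y) - B*sinh(kappa*y)` with
#' `A = (zeta2*sinh(kappa*h1) - zeta1*sinh(kappa*h2)) / sinh(kappa*(h1-h2))`
#' and `B` the analogous cosh combination. The coefficients are evaluated in
#' scaled-exponential form, so wide channels or thin double layers
#' (large `kappa*(h2-h1)`) do not overflow; an error is raised only when the
#' subsequent `cosh(kappa*y)` evaluation itself would overflow
#' (`kappa * max(|h1|, |h2|) > 700`), with the advice to reduce
#' `kappa` times the channel width.
#'
#' @param ek An [electrokinetic_params()].
#' @param h1,h2 Wall positions, `h1 < h2`.
#' @return An object of class `potential_coefficients` with fields `A`, `B`.
#' @export
#' @examples
#' w <- wall_positions(0, dimensionless_geometry(0.5, 0.5))
#' potential_coefficients(electrokinetic_params(kappa = 2), w$h1, w$h2)
potential_coefficients <- function(ek, h1, h2) {
  stopifnot(inherits(ek, "electrokinetic_params"))
  if (!(h1 < h2)) stop("`h1` must be strictly less than `h2`", call. = FALSE)
  k <- ek$kappa
  if (k * max(abs(h1), abs(h2)) > 700)
    stop("kappa * channel width too large: hyperbolic evaluation would ",
         "overflow; reduce kappa or the wall positions", call. = FALSE)
  w <- h2 - h1
  A <- ek$zeta1 * .sinh_ratio(k * h2, k * w) -
       ek$zeta2 * .sinh_ratio(k * h1, k * w)
  B <- ek$zeta1 * .cosh_sinh_ratio(k * h2, k * w) -
       ek$zeta2 * .cosh_sinh_ratio(k * h1, k * w)
  structure(list(A = A, B = B), class = "potential_coefficients")
}

#' Electric-double-layer potential profile
#'
#' `phi(y) = A*cosh(kappa*y) - B*sinh(kappa*y)`; satisfies
#' `phi'' = kappa^2 * phi` identically.
#'
#' @param y Transverse coordinate; vectorised.
#' @param coeffs A [potential_coefficients()].
#' @param kappa Electroosmotic parameter.
#' @return Numeric vector of potential values.
#' @export
potential <- function(y, coeffs, kappa) {
  stopifnot(inherits(coeffs, "potential_coefficients"))
  coeffs$A * cosh(kappa * y) - coeffs$B * sinh(kappa * y)
}

#' Transverse derivative of the double-layer potential
#'
#' `phi'(y) = kappa * (A*sinh(kappa*y) - B*cosh(kappa*y))`.
#'
#' @inheritParams potential
#' @return Numeric vector `phi'(y)`.
#' @export
potential_deriv <- function(y, coeffs, kappa) {
  stopifnot(inherits(coeffs, "potential_coefficients"))
  kappa * (coeffs$A * sinh(kappa * y) - coeffs$B * cosh(kappa * y))
}

#' Electroosmotic body force in the momentum balance
#'
#' The momentum source contributed by the applied axial field acting on the
#' double-layer charge: `kappa^3 * U_HS * (A*sinh(kappa*y) - B*cosh(kappa*y))`,
#' identically equal to `U_HS * kappa^2 * phi'(y)`.
#'
#' @inheritParams potential
#' @param U_HS Helmholtz--Smoluchowski velocity.
#' @return Numeric vector of momentum-source values.
#' @export
body_force <- function(y, coeffs, kappa, U_HS) {
  stopifnot(inherits(coeffs, "potential_coefficients"))
  kappa^3 * U_HS * (coeffs$A * sinh(kappa * y) - coeffs$B * cosh(kappa * y))
}

#' @export
print.electrokinetic_params <- function(x, ...) {
  cat(sprintf("Electrokinetic parameters: kappa = %g, zeta1 = %g, zeta2 = %g, U_HS = %g\n",
              x$kappa, x$zeta1, x$zeta2, x$U_HS))
  invisible(x)
}
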