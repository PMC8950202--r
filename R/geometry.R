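#' Dimensional peristaltic channel
#'
#' Describes the physical (dimensional) asymmetric channel: a pair of flexible
#' walls carrying travelling sinusoidal contraction waves of speed `c` and
#' wavelength `lambda`, offset by a phase difference `phi`.
#'
#' @param d Channel half-width (m), `> 0`.
#' @param a1 Left-wall wave amplitude (m), `>= 0`.
#' @param a2 Right-wall wave amplitude (m), `>= 0`.
#' @param lambda Wavelength (m), `> 0`.
#' @param c Wave speed (m/s), `> 0`.
#' @param phi Phase difference between the walls (rad), in `[0, pi]`.
#'
#' @return An object of class `dimensional_channel`.
#' @seealso [dimensional_walls()], [as_dimensionless()]
#' @export
#' @examples
#' ch <- dimensional_channel(d = 1e-3, a1 = 5e-4, a2 = 5e-4,
#'                           lambda = 1e-2, c = 1e-2)
#' dimensional_walls(0, 0, ch)
dimensional_channel <- function(d, a1, a2, lambda, c, phi = 0) {
  stopifnot(is.numeric(d), is.numeric(a1), is.numeric(a2),
            is.numeric(lambda), is.numeric(c), is.numeric(phi))
  if (d <= 0) stop("channel half-width `d` must be positive", call. = FALSE)
  if (a1 < 0 || a2 < 0) stop("wave amplitudes must be non-negative", call. = FALSE)
  if (lambda <= 0) stop("wavelength `lambda` must be positive", call. = FALSE)
  if (c <= 0) stop("wave speed `c` must be positive", call. = FALSE)
  if (phi < 0 || phi > pi) stop("phase difference `phi` must lie in [0, pi]", call. = FALSE)
  structure(list(d = d, a1 = a1, a2 = a2, lambda = lambda, c = c, phi = phi),
            class = "dimensional_channel")
}

#' Dimensionless channel geometry
#'
#' Wall kinematics in wave-frame coordinates scaled by the half-width `d`
#' (transverse) and wavelength (axial). The left and right walls are
#' `h1(x) = -1 - a*cos^2(pi*x + phi)` and `h2(x) = 1 + b*cos^2(pi*x)`, so the
#' gap never closes: `h2 - h1 >= 2` for any `a, b >= 0`.
#'
#' The defaults `a = b = 0.5`, `phi = 0` are the package's reference geometry,
#' chosen as a moderate symmetric occlusion; they are a package convention,
#' not a literature-prescribed value.
#'
#' @param a Left amplitude ratio (amplitude / half-width), `>= 0`.
#' @param b Right amplitude ratio, `>= 0`.
#' @param phi Phase difference (rad), in `[0, pi]`.
#'
#' @return An object of class `dimensionless_geometry`.
#' @seealso [wall_positions()]
#' @export
dimensionless_geometry <- function(a = 0.5, b = 0.5, phi = 0) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(phi))
  if (a < 0 || b < 0) stop("amplitude ratios `a`, `b` must be non-negative", call. = FALSE)
  if (phi < 0 || phi > pi) stop("phase difference `phi` must lie in [0, pi]", call. = FALSE)
  structure(list(a = a, b = b, phi = phi), class = "dimensionless_geometry")
}

#' Convert a dimensional channel to its dimensionless geometry
#'
#' Amplitude ratios are amplitudes over the half-width: `a = a1/d`, `b = a2/d`.
#'
#' @param ch A [dimensional_channel()].
#' @return A [dimensionless_geometry()].
#' @export
as_dimensionless <- function(ch) {
  stopifnot(inherits(ch, "dimensional_channel"))
  dimensionless_geometry(a = ch$a1 / ch$d, b = ch$a2 / ch$d, phi = ch$phi)
}

#' Dimensionless wall positions
#'
#' @param x Dimensionless axial coordinate (wave frame); vectorised.
#' @param geom A [dimensionless_geometry()].
#'
#' @return A list with components `h1` (left wall, `<= -1`) and `h2`
#'   (right wall, `>= 1`), each the same length as `x`. Both are 1-periodic
#'   in `x`.
#' @export
#' @examples
#' wall_positions(0, dimensionless_geometry(a = 0.5, b = 0.5))
wall_positions <- function(x, geom = dimensionless_geometry()) {
  stopifnot(inherits(geom, "dimensionless_geometry"), is.numeric(x))
  list(h1 = -1 - geom$a * cos(pi * x + geom$phi)^2,
       h2 =  1 + geom$b * cos(pi * x)^2)
}

#' Dimensional wall positions
#'
#' Lab-frame wall laws `H1(X, t)`, `H2(X, t)`; dividing by `d` and
#' substituting `x = (X - c*t)/lambda` recovers [wall_positions()].
#'
#' @param X Axial position (m); vectorised.
#' @param t Time (s).
#' @param ch A [dimensional_channel()].
#' @return A list with components `H1` and `H2` (m).
#' @export
dimensional_walls <- function(X, t, ch) {
  stopifnot(inherits(ch, "dimensional_channel"))
  arg <- pi * (X - ch$c * t) / ch$lambda
  list(H1 = -ch$d - ch$a1 * cos(arg + ch$phi)^2,
       H2 =  ch$d + ch$a2 * cos(arg)^2)
}

#' Convert between fixed-frame and wave-frame flow rates
#'
#' The time-mean fixed-frame flow rate `Q` and the wave-frame flow rate `F`
#' are related by `Q = F + 2 + (a + b)/2`. Supply exactly one of the two;
#' the other is returned.
#'
#' @param Q Fixed-frame time-mean flow rate, or `NULL`.
#' @param F Wave-frame flow rate, or `NULL`.
#' @param geom A [dimensionless_geometry()].
#' @return A single number: `F` when `Q` was supplied, `Q` otherwise.
#' @export
#' @examples
#' flow_rate_relation(Q = 3.5, geom = dimensionless_geometry(0.5, 0.5)) # F = 1
flow_rate_relation <- function(Q = NULL, F = NULL, geom = dimensionless_geometry()) {
  stopifnot(inherits(geom, "dimensionless_geometry"))
  if (is.null(Q) == is.null(F))
    stop("supply exactly one of `Q` and `F`", call. = FALSE)
  offset <- 2 + (geom$a + geom$b) / 2
  if (is.null(F)) Q - offset else F + offset
}

#' @export
print.dimensionless_geometry <- function(x, ...) {
  cat(sprintf("Dimensionless peristaltic geometry: a = %g, b = %g, phi = %g rad\n",
              x$a, x$b, x$phi))
  invisible(x)
}

#' @export
print.dimensional_channel <- function(x, ...) {
  cat(sprintf(paste0("Dimensional peristaltic channel: d = %g m, a1 = %g m, ",
                     "a2 = %g m,\n  lambda = %g m, c = %g m/s, phi = %g rad\n"),
              x$d, x$a1, x$a2, x$lambda, x$c, x$phi))
  invisible(x)
}
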