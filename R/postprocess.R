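#' Wall shear stress
#'
#' Dimensionless shear stress `tau_s = (mu_nf/mu_f) * du/dy` evaluated at the
#' left wall (`y = h1`), with `u = psi'` in the wave frame, i.e.
#' `tau_s = mu_r * psi''(h1)`. A right-wall variant is available for symmetry
#' checks.
#'
#' @param sol A converged [solve_station()] (or [fd_oracle_solve()]) result.
#' @param mix A [mixture_ratios()][mixture_properties()]; defaults to the one
#'   stored in `sol`.
#' @param wall `"left"` (default, the reported convention) or `"right"`.
#' @return A single dimensionless shear-stress value.
#' @export
shear_stress <- function(sol, mix = sol$mix, wall = c("left", "right")) {
  wall <- match.arg(wall)
  j <- if (wall == "left") 1L else ncol(sol$states)
  unname(mix$mu_r * sol$states["d2psi", j])
}

#' Velocity profiles in both frames
#'
#' The wave-frame axial velocity is `u_wave = psi'`; the lab-frame velocity
#' follows from the frame shift `u = U - c`, so `u_lab = u_wave + 1`.
#' No-slip holds in the lab frame: `u_lab = 0`, i.e. `u_wave = -1`, at both
#' walls.
#'
#' @param sol A converged station solution.
#' @return A data frame with columns `y`, `u_wave`, `u_lab`.
#' @export
velocity_profiles <- function(sol) {
  uw <- sol$states["dpsi", ]
  data.frame(y = sol$grid, u_wave = uw, u_lab = uw + 1)
}

#' Heat-transfer diagnostic at the left wall
#'
#' A package-defined convention (exposed as an optional diagnostic only):
#' `Nu = -(k_r + Rn*Pr) * theta'(h1)`, the conductive-plus-radiative wall
#' heat flux scaled by the base-fluid conductivity.
#'
#' @param sol A converged station solution.
#' @param p,mix Model parameters and mixture ratios; default to those stored
#'   in `sol`.
#' @return A single dimensionless heat-flux value.
#' @export
heat_flux_diagnostic <- function(sol, p = sol$params, mix = sol$mix) {
  unname(-(mix$k_r + p$Rn * p$Pr) * sol$states["dtheta", 1L])
}

#' Full-field data frame of a station solution
#'
#' @param x A `station_solution`.
#' @param row.names,optional,... Passed over from the generic (unused).
#' @return Data frame with columns `x`, `y`, `psi`, `u_wave`, `u_lab`,
#'   `theta`, `sigma`, `chi`.
#' @export
as.data.frame.station_solution <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  uw <- x$states["dpsi", ]
  data.frame(x = x$x, y = x$grid, psi = x$states["psi", ],
             u_wave = uw, u_lab = uw + 1,
             theta = x$states["theta", ], sigma = x$states["sigma", ],
             chi = x$states["chi", ])
}

#' @export
as.data.frame.fd_station_solution <- as.data.frame.station_solution

#' Sweep a parameter across solver runs
#'
#' Re-solves the station problem for each value of one varied quantity and
#' collects profiles in long format plus per-station wall scalars. The varied
#' quantity may be any [model_parameters()] field, any
#' [electrokinetic_params()] field, the particle volume fraction `phi1`, or
#' the particle `shape` (character values).
#'
#' @param vary Name of the quantity to vary.
#' @param values Vector of values (character for `shape`).
#' @param p,geom,ek Baseline inputs.
#' @param phi1,shape Baseline nanofluid state, re-mixed when `vary` is
#'   `"phi1"` or `"shape"`.
#' @param xs Axial stations to solve at (default 0).
#' @param opts A [solver_options()].
#'
#' @return A long-format data frame with columns `param`, `value`, `x`, `y`,
#'   `field` (`psi`, `u_wave`, `u_lab`, `theta`, `sigma`, `chi`) and `val`;
#'   attribute `"scalars"` holds a data frame of per-run `x`, `tau_s`, `Nu`.
#'   Empty `values` give an empty table. A failed solve is re-raised with the
#'   offending parameter value named.
#' @export
#' @examples
#' \donttest{
#' tab <- parameter_sweep("M", c(0, 2), xs = 0)
#' attr(tab, "scalars")
#' }
parameter_sweep <- function(vary, values, p = model_parameters(),
                            geom = dimensionless_geometry(),
                            ek = electrokinetic_params(),
                            phi1 = 0.05, shape = "bricks", xs = 0,
                            opts = solver_options()) {
  stopifnot(is.character(vary), length(vary) == 1L)
  known <- c(names(unclass(p)), names(unclass(ek)), "phi1", "shape")
  if (!vary %in% known)
    stop("unknown sweep parameter: ", vary, call. = FALSE)
  rows <- list(); scal <- list()
  for (v in values) {
    pv <- p; ekv <- ek
    mixv <- mixture_properties(phi1, particle_shape(shape))
    if (vary %in% names(unclass(p))) {
      pl <- unclass(p); pl[[vary]] <- v
      pv <- do.call(model_parameters, pl)
    } else if (vary %in% names(unclass(ek))) {
      el <- unclass(ek); el[[vary]] <- v
      ekv <- do.call(electrokinetic_params, el)
    } else if (vary == "phi1") {
      mixv <- mixture_properties(v, particle_shape(shape))
    } else {
      mixv <- mixture_properties(phi1, particle_shape(v))
    }
    for (xst in xs) {
      sol <- tryCatch(
        solve_station(xst, pv, geom, mixv, ekv, opts),
        error = function(e)
          stop(sprintf("sweep failed at %s = %s, x = %g: %s",
                       vary, format(v), xst, conditionMessage(e)),
               call. = FALSE))
      df <- as.data.frame(sol)
      long <- data.frame(
        param = vary, value = v, x = xst,
        y = rep(df$y, 6L),
        field = rep(c("psi", "u_wave", "u_lab", "theta", "sigma", "chi"),
                    each = nrow(df)),
        val = c(df$psi, df$u_wave, df$u_lab, df$theta, df$sigma, df$chi))
      rows[[length(rows) + 1L]] <- long
      scal[[length(scal) + 1L]] <- data.frame(
        param = vary, value = v, x = xst,
        tau_s = shear_stress(sol), Nu = heat_flux_diagnostic(sol))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(param = character(), value = numeric(), x = numeric(),
               y = numeric(), field = character(), val = numeric())
  attr(out, "scalars") <- if (length(scal)) do.call(rbind, scal) else
    data.frame(param = character(), value = numeric(), x = numeric(),
               tau_s = numeric(), Nu = numeric())
  out
}

#' Plot a swept field, one curve per parameter value
#'
#' Minimal base-graphics view of a [parameter_sweep()] table.
#'
#' @param tab A [parameter_sweep()] result.
#' @param field Field to draw (default `"u_wave"`).
#' @param x Station to draw (default the first present).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the wide matrix that was drawn.
#' @export
plot_sweep <- function(tab, field = "u_wave", x = tab$x[1L], ...) {
  sub <- tab[tab$field == field & tab$x == x, ]
  if (!nrow(sub)) stop("nothing to plot for that field/station", call. = FALSE)
  vals <- unique(sub$value)
  yy <- sort(unique(sub$y))
  wide <- vapply(vals, function(v) {
    si <- sub[sub$value == v, ]
    si$val[order(si$y)]
  }, numeric(length(yy)))
  graphics::matplot(yy, wide, type = "l", lty = 1,
                    xlab = "y", ylab = field, ...)
  graphics::legend("topright", legend = paste(sub$param[1L], "=", vals),
                   lty = 1, col = seq_along(vals), bty = "n", cex = 0.8)
  invisible(wide)
}
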