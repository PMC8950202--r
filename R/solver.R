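#' Solver options for the collocation boundary-value solver
#'
#' @param tol Target maximum interior ODE residual on the dense check grid
#'   (absolute, default `1e-8`).
#' @param max_nodes Mesh-size cap for refinement (default 6401).
#' @param n_init Initial number of mesh points (default 101, must be
#'   `>= 11`; odd values keep the channel midpoint on the grid).
#' @param continuation Enable the parameter-continuation fallback when a cold
#'   Newton start fails (default `TRUE`).
#' @param cont_steps Number of geometric continuation steps (default 4).
#' @param max_iter Newton iteration cap per solve (default 40).
#'
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-8, max_nodes = 6401, n_init = 101,
                           continuation = TRUE, cont_steps = 4, max_iter = 40) {
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (n_init < 11) stop("`n_init` must be at least 11", call. = FALSE)
  structure(list(tol = tol, max_nodes = max_nodes, n_init = n_init,
                 continuation = continuation, cont_steps = cont_steps,
                 max_iter = max_iter),
            class = "solver_options")
}

.state_names <- c("psi", "dpsi", "d2psi", "d3psi", "theta", "dtheta",
                  "sigma", "dsigma", "chi", "dchi")

# Cubic stream function through the four psi boundary rows (the exact
# solution of the momentum equation with M = Gr = U_HS = 0) plus linear
# temperature/concentration/microorganism ramps: the trivial-limit closed
# forms used as the cold-start guess.
.initial_guess <- function(ygrid, h1, h2, F) {
  basis <- function(y) cbind(1, y, y^2, y^3)
  dbasis <- function(y) cbind(0, 1, 2 * y, 3 * y^2)
  Amat <- rbind(basis(h1), dbasis(h1), basis(h2), dbasis(h2))
  cf <- solve(Amat, c(-F / 2, -1, F / 2, -1))
  w <- h2 - h1
  lin <- (ygrid - h1) / w
  Y <- rbind(drop(basis(ygrid) %*% cf),
             drop(dbasis(ygrid) %*% cf),
             drop(cbind(0, 0, 2, 6 * ygrid) %*% cf),
             rep(6 * cf[4], length(ygrid)),
             lin, rep(1 / w, length(ygrid)),
             lin, rep(1 / w, length(ygrid)),
             lin, rep(1 / w, length(ygrid)))
  rownames(Y) <- .state_names
  Y
}

# Residual of the 3-stage Lobatto IIIA (Simpson/Hermite) collocation scheme:
# 10 boundary rows followed by 10 rows per interval.
.colloc_resid <- function(ygrid, Y, p, mix, ek, coeffs) {
  N <- length(ygrid)
  h <- diff(ygrid)
  Fi <- .rhs_eval(ygrid, Y, p, mix, ek, coeffs)
  Yl <- Y[, -N, drop = FALSE]; Yr <- Y[, -1L, drop = FALSE]
  Fl <- Fi[, -N, drop = FALSE]; Fr <- Fi[, -1L, drop = FALSE]
  Ymid <- (Yl + Yr) / 2 + t(t(Fl - Fr) * (h / 8))
  ymid <- (ygrid[-N] + ygrid[-1L]) / 2
  Fmid <- .rhs_eval(ymid, Ymid, p, mix, ek, coeffs)
  Rblk <- Yr - Yl - t(t(Fl + 4 * Fmid + Fr) * (h / 6))
  c(boundary_residual(Y[, 1L], Y[, N], p), as.vector(Rblk))
}

.colloc_jac <- function(ygrid, Y, p, mix, ek, coeffs) {
  N <- length(ygrid)
  h <- diff(ygrid)
  Fi <- .rhs_eval(ygrid, Y, p, mix, ek, coeffs)
  Ji <- .rhs_jacobian(ygrid, Y, p, mix, ek, coeffs)
  Yl <- Y[, -N, drop = FALSE]; Yr <- Y[, -1L, drop = FALSE]
  Fl <- Fi[, -N, drop = FALSE]; Fr <- Fi[, -1L, drop = FALSE]
  Ymid <- (Yl + Yr) / 2 + t(t(Fl - Fr) * (h / 8))
  ymid <- (ygrid[-N] + ygrid[-1L]) / 2
  Jm <- .rhs_jacobian(ymid, Ymid, p, mix, ek, coeffs)
  I10 <- diag(10)
  Av <- array(0, c(10L, 10L, N - 1L))
  Bv <- array(0, c(10L, 10L, N - 1L))
  for (j in seq_len(N - 1L)) {
    Jl <- Ji[, , j]; Jr <- Ji[, , j + 1L]; Jc <- Jm[, , j]; hj <- h[j]
    Av[, , j] <- -I10 - (hj / 6) * (Jl + 4 * Jc %*% (I10 / 2 + (hj / 8) * Jl))
    Bv[, , j] <-  I10 - (hj / 6) * (Jr + 4 * Jc %*% (I10 / 2 - (hj / 8) * Jr))
  }
  brow <- rep(1:10, times = 10)
  bcol <- rep(1:10, each = 10)
  rows_blk <- rep((0:(N - 2L)) * 10L, each = 100L) + 10L + brow
  colsA <- rep((0:(N - 2L)) * 10L, each = 100L) + bcol
  bc_i <- 1:10
  bc_j <- c(1L, 2L, 5L, 7L, 9L, (N - 1L) * 10L + c(1L, 2L, 5L, 7L, 9L))
  Matrix::sparseMatrix(i = c(bc_i, rows_blk, rows_blk),
                       j = c(bc_j, colsA, colsA + 10L),
                       x = c(rep(1, 10), as.vector(Av), as.vector(Bv)),
                       dims = c(10L * N, 10L * N))
}

# Damped Newton on the collocation equations. Iterates to the roundoff floor
# (target 1e-13 * scale): a looser algebraic tolerance would leave an O(tol/h)
# floor in the interpolant's interior residual. Stagnation at a residual below
# 1e-9 * scale still counts as converged (roundoff-limited).
.newton_colloc <- function(ygrid, Y, p, mix, ek, coeffs, max_iter = 40) {
  R <- .colloc_resid(ygrid, Y, p, mix, ek, coeffs)
  nr <- max(abs(R))
  iters <- 0L
  for (it in seq_len(max_iter)) {
    scale <- 1 + max(abs(Y))
    if (!is.finite(nr)) return(list(Y = Y, iterations = iters, converged = FALSE))
    if (nr < 1e-13 * scale)
      return(list(Y = Y, iterations = iters, converged = TRUE, resid = nr))
    J <- .colloc_jac(ygrid, Y, p, mix, ek, coeffs)
    dz <- tryCatch(as.numeric(Matrix::solve(J, -R)),
                   error = function(e) NULL)
    if (is.null(dz) || any(!is.finite(dz)))
      return(list(Y = Y, iterations = iters, converged = FALSE))
    dY <- matrix(dz, nrow = 10L)
    lam <- 1
    accepted <- FALSE
    for (k in 1:12) {
      Yn <- Y + lam * dY
      Rn <- .colloc_resid(ygrid, Yn, p, mix, ek, coeffs)
      nrn <- max(abs(Rn))
      if (is.finite(nrn) && nrn < nr) {
        accepted <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!accepted)
      return(list(Y = Y, iterations = iters,
                  converged = nr < 1e-9 * scale, resid = nr))
    Y <- Yn; R <- Rn; nr <- nrn
    iters <- it
  }
  list(Y = Y, iterations = iters, converged = nr < 1e-9 * (1 + max(abs(Y))),
       resid = nr)
}

# Quintic Hermite interpolation machinery: value/slope data at the interval
# ends and collocation midpoint determine a degree-5 polynomial per interval
# and state. Coefficients are monomials in the local coordinate t in [0, 1].
.quintic_Minv <- solve(rbind(
  c(1, 0, 0, 0, 0, 0),
  c(0, 1, 0, 0, 0, 0),
  c(1, 0.5, 0.25, 0.125, 0.0625, 0.03125),
  c(0, 1, 1, 0.75, 0.5, 0.3125),
  c(1, 1, 1, 1, 1, 1),
  c(0, 1, 2, 3, 4, 5)))

.quintic_coef <- function(ygrid, Y, p, mix, ek, coeffs) {
  N <- length(ygrid)
  h <- diff(ygrid)
  Fi <- .rhs_eval(ygrid, Y, p, mix, ek, coeffs)
  Yl <- Y[, -N, drop = FALSE]; Yr <- Y[, -1L, drop = FALSE]
  Fl <- Fi[, -N, drop = FALSE]; Fr <- Fi[, -1L, drop = FALSE]
  Ymid <- (Yl + Yr) / 2 + t(t(Fl - Fr) * (h / 8))
  ymid <- (ygrid[-N] + ygrid[-1L]) / 2
  Fmid <- .rhs_eval(ymid, Ymid, p, mix, ek, coeffs)
  hs <- rep(h, each = 10L)
  rhs <- rbind(as.vector(Yl), as.vector(Fl) * hs,
               as.vector(Ymid), as.vector(Fmid) * hs,
               as.vector(Yr), as.vector(Fr) * hs)
  .quintic_Minv %*% rhs              # 6 x (10 * (N - 1))
}

# Evaluate the quintic interpolant (and derivative) at local coordinate t for
# every interval; returns 10 x (N-1) matrices.
.quintic_eval <- function(C, h, tloc) {
  tp <- c(1, tloc, tloc^2, tloc^3, tloc^4, tloc^5)
  dtp <- c(0, 1, 2 * tloc, 3 * tloc^2, 4 * tloc^3, 5 * tloc^4)
  K <- ncol(C)
  S <- matrix(drop(tp %*% C), nrow = 10L)
  Sp <- matrix(drop(dtp %*% C), nrow = 10L) / matrix(rep(h, each = 10L), nrow = 10L)
  list(S = S, Sp = Sp)
}

# Max-abs interior residual |S'(y) - f(S(y))| of the interpolated solution on
# a dense check grid (4 points per interval).
.ode_residual <- function(ygrid, Y, p, mix, ek, coeffs,
                          tcheck = c(0.125, 0.375, 0.625, 0.875)) {
  C <- .quintic_coef(ygrid, Y, p, mix, ek, coeffs)
  N <- length(ygrid)
  h <- diff(ygrid)
  worst <- 0
  for (tl in tcheck) {
    ev <- .quintic_eval(C, h, tl)
    yv <- ygrid[-N] + tl * h
    Fv <- .rhs_eval(yv, ev$S, p, mix, ek, coeffs)
    worst <- max(worst, max(abs(ev$Sp - Fv)))
  }
  worst
}

# Joint ramp of the forcing/nonlinearity parameters used by continuation:
# M^2, Gr, xi, Pe, U_HS and Nt are scaled by tfrac (Nb stays fixed so the
# Nt/Nb ratio shrinks smoothly with the ramp).
.ramp_params <- function(p, ek, tfrac) {
  pc <- unclass(p)
  pc$M <- p$M * sqrt(tfrac)
  pc$Gr <- p$Gr * tfrac
  pc$xi <- p$xi * tfrac
  pc$Pe <- p$Pe * tfrac
  pc$Nt <- p$Nt * tfrac
  ekc <- electrokinetic_params(kappa = ek$kappa, zeta1 = ek$zeta1,
                               zeta2 = ek$zeta2, U_HS = ek$U_HS * tfrac)
  list(p = do.call(model_parameters, pc), ek = ekc)
}

#' Solve the ten-state boundary-value problem at one axial station
#'
#' Discretises the coupled reduced system with 3-stage Lobatto IIIA
#' (fourth-order) collocation on a mesh spanning `[h1(x), h2(x)]` and solves
#' the nonlinear algebraic system by damped Newton iteration. If the cold
#' start from the trivial-limit closed forms fails, the forcing parameters
#' (`M^2`, `Gr`, `xi`, `Pe`, `U_HS`, `Nt`) are ramped jointly from zero in
#' geometric continuation steps. After convergence the mesh is doubled until
#' the interior residual of the quintic-Hermite interpolant on a 4x-dense
#' check grid falls below `opts$tol` (or `opts$max_nodes` is reached, with a
#' warning).
#'
#' @param x Dimensionless axial station (default 0).
#' @param p A [model_parameters()].
#' @param geom A [dimensionless_geometry()].
#' @param mix A [mixture_ratios()][mixture_properties()].
#' @param ek An [electrokinetic_params()].
#' @param opts A [solver_options()].
#'
#' @return An object of class `station_solution`: fields `x`, `grid`
#'   (ascending from `h1` to `h2`), `states` (`10 x n` matrix, rows
#'   `psi, dpsi, d2psi, d3psi, theta, dtheta, sigma, dsigma, chi, dchi`),
#'   `h1`, `h2`, `ode_residual`, `bc_residual`, `diagnostics` (iterations,
#'   mesh size, continuation path, refinements) and the inputs used.
#' @seealso [fd_oracle_solve()], [closed_form_momentum()], [shear_stress()]
#' @export
#' @examples
#' sol <- solve_station(p = model_parameters(M = 2, Gr = 0, Nt = 0, Nb = 0,
#'                                           xi = 0, Pe = 0))
#' sol
solve_station <- function(x = 0, p = model_parameters(),
                          geom = dimensionless_geometry(),
                          mix = mixture_properties(0.05),
                          ek = electrokinetic_params(),
                          opts = solver_options()) {
  stopifnot(inherits(p, "model_parameters"), inherits(opts, "solver_options"))
  w <- wall_positions(x, geom)
  h1 <- w$h1; h2 <- w$h2
  coeffs <- potential_coefficients(ek, h1, h2)
  ygrid <- seq(h1, h2, length.out = opts$n_init)
  Y <- .initial_guess(ygrid, h1, h2, p$F)

  cont_path <- numeric(0)
  total_iter <- 0L
  res <- .newton_colloc(ygrid, Y, p, mix, ek, coeffs, opts$max_iter)
  total_iter <- total_iter + res$iterations
  if (!res$converged && opts$continuation) {
    steps <- 2^(-(opts$cont_steps - 1):0)   # e.g. 1/8, 1/4, 1/2, 1
    Yc <- Y
    last_ok <- 0
    for (tfrac in steps) {
      rp <- .ramp_params(p, ek, tfrac)
      cfc <- potential_coefficients(rp$ek, h1, h2)
      res <- .newton_colloc(ygrid, Yc, rp$p, mix, rp$ek, cfc, opts$max_iter)
      total_iter <- total_iter + res$iterations
      if (!res$converged)
        stop(sprintf(paste0("solver failed to converge; last successful ",
                            "continuation fraction: %g (of target 1)"), last_ok),
             call. = FALSE)
      Yc <- res$Y
      last_ok <- tfrac
      cont_path <- c(cont_path, tfrac)
    }
    res$Y <- Yc
  }
  if (!res$converged)
    stop("solver failed to converge from the cold start and continuation is disabled",
         call. = FALSE)
  Y <- res$Y

  refinements <- 0L
  repeat {
    rr <- .ode_residual(ygrid, Y, p, mix, ek, coeffs)
    if (rr < opts$tol) break
    Nnew <- 2L * length(ygrid) - 1L
    if (Nnew > opts$max_nodes) {
      warning(sprintf("mesh cap reached (n = %d); interior residual %.3g above tol %.3g",
                      length(ygrid), rr, opts$tol), call. = FALSE)
      break
    }
    C <- .quintic_coef(ygrid, Y, p, mix, ek, coeffs)
    h <- diff(ygrid)
    mid <- .quintic_eval(C, h, 0.5)$S
    ygrid2 <- numeric(Nnew)
    ygrid2[seq(1L, Nnew, by = 2L)] <- ygrid
    ygrid2[seq(2L, Nnew - 1L, by = 2L)] <- (ygrid[-length(ygrid)] + ygrid[-1L]) / 2
    Y2 <- matrix(0, 10L, Nnew)
    Y2[, seq(1L, Nnew, by = 2L)] <- Y
    Y2[, seq(2L, Nnew - 1L, by = 2L)] <- mid
    ygrid <- ygrid2
    res <- .newton_colloc(ygrid, Y2, p, mix, ek, coeffs, opts$max_iter)
    total_iter <- total_iter + res$iterations
    if (!res$converged)
      stop("Newton iteration diverged during mesh refinement", call. = FALSE)
    Y <- res$Y
    refinements <- refinements + 1L
  }
  rownames(Y) <- .state_names
  bc <- max(abs(boundary_residual(Y[, 1L], Y[, ncol(Y)], p)))
  structure(list(
    x = x, grid = ygrid, states = Y, h1 = h1, h2 = h2,
    ode_residual = .ode_residual(ygrid, Y, p, mix, ek, coeffs),
    bc_residual = bc,
    interp = list(C = .quintic_coef(ygrid, Y, p, mix, ek, coeffs),
                  h = diff(ygrid)),
    diagnostics = list(iterations = total_iter, mesh_size = length(ygrid),
                       continuation = cont_path, refinements = refinements,
                       method = "lobatto3a-collocation"),
    params = p, mix = mix, ek = ek, geom = geom, coeffs = coeffs),
    class = "station_solution")
}

#' Evaluate a station solution at arbitrary transverse positions
#'
#' Uses the per-interval quintic Hermite interpolant of the collocation
#' solution (the same polynomial whose residual is reported as
#' `ode_residual`).
#'
#' @param object A `station_solution` from [solve_station()].
#' @param y Positions in `[h1, h2]`.
#' @param ... Unused.
#' @return A `10 x length(y)` matrix of interpolated states.
#' @export
predict.station_solution <- function(object, y, ...) {
  grid <- object$grid
  N <- length(grid)
  tolr <- 1e-12 * (object$h2 - object$h1)
  if (any(y < object$h1 - tolr | y > object$h2 + tolr))
    stop("evaluation points must lie within [h1, h2]", call. = FALSE)
  y <- pmin(pmax(y, object$h1), object$h2)
  j <- pmin(pmax(findInterval(y, grid), 1L), N - 1L)
  out <- matrix(0, 10L, length(y), dimnames = list(.state_names, NULL))
  h <- object$interp$h
  C <- object$interp$C
  for (m in seq_along(y)) {
    jm <- j[m]
    tl <- (y[m] - grid[jm]) / h[jm]
    tp <- c(1, tl, tl^2, tl^3, tl^4, tl^5)
    out[, m] <- drop(tp %*% C[, (jm - 1L) * 10L + 1:10])
  }
  out
}

#' @export
print.station_solution <- function(x, ...) {
  cat(sprintf("Station solution at x = %g: y in [%.4g, %.4g], %d mesh points\n",
              x$x, x$h1, x$h2, length(x$grid)))
  cat(sprintf("  method: %s, ODE residual %.3g, BC residual %.3g\n",
              x$diagnostics$method, x$ode_residual, x$bc_residual))
  mid <- predict(x, (x$h1 + x$h2) / 2)
  cat(sprintf("  midpoint: u_wave = %.6g, theta = %.6g, sigma = %.6g, chi = %.6g\n",
              mid["dpsi", 1], mid["theta", 1], mid["sigma", 1], mid["chi", 1]))
  invisible(x)
}
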