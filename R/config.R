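#' Default run configuration
#'
#' The fully resolved default configuration: reference geometry
#' `a = b = 0.5`, `phi = 0`, station `x = 0`, fixed-frame flow rate
#' `Q = 3.5`, 5\% brick-shaped gold particles, and the mid-range dimensionless
#' groups of [model_parameters()] / [electrokinetic_params()].
#'
#' @return A nested named list (the canonical config structure).
#' @export
default_config <- function() {
  list(
    geometry = list(a = 0.5, b = 0.5, phi = 0, x = 0),
    flow = list(Q = 3.5),
    nanofluid = list(phi1 = 0.05, shape = "bricks"),
    electro = list(kappa = 2, zeta1 = 1, zeta2 = 1, U_HS = 1),
    model = list(M = 2, Gr = 2, Nr = 1, Rb = 1, Rn = 0.4, Pr = 21,
                 Nb = 0.5, Nt = 1, Sc = 1, xi = 1, beta = 1, E = 1,
                 n = 0.5, Pe = 0.5, Omega = 1),
    solver = list(tol = 1e-8, max_nodes = 6401, n_init = 101,
                  continuation = TRUE),
    sweep = list(parameter = "M", values = c(0, 2, 4, 6), xs = 0),
    output = list(profile = "profile.csv", meta = "run.json",
                  plots = FALSE))
}

# Literature parameter ranges; configs outside them warn, never fail.
.param_ranges <- list(
  M = c(0, 6), Gr = c(0, 6), U_HS = c(-3, 9), Rn = c(0.1, 0.7),
  Nt = c(1, 9), Nb = c(0.1, 0.9), E = c(1, 4), beta = c(0, 3),
  Pe = c(0, 0.9), kappa = c(2, 2.3), zeta1 = c(1, 1.6),
  Rb = c(1, 1.6), Nr = c(1, 1.6))

.merge_config <- function(defaults, user, path = character(0)) {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown config key: ", paste(c(path, nm), collapse = "."),
           call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", paste(c(path, nm), collapse = "."),
             " must be a section", call. = FALSE)
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, by file extension) configuration, applies the
#' package defaults for every key not given, rejects unknown keys, enforces
#' structural invariants (exactly one of `flow.Q`/`flow.F`; `Nb = 0` only
#' with `Nt = 0`) and warns -- without failing -- when a parameter lies
#' outside its literature range (e.g. Hartmann number 0--6). An empty file
#' yields the full default set.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` configuration file.
#' @return A validated config list of class `run_config` with the resolved
#'   wave-frame flow rate in `flow$F` and `flow$Q`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  defaults <- default_config()
  has_Q <- !is.null(user$flow$Q); has_F <- !is.null(user$flow$F)
  if (has_Q && has_F)
    stop("config must give exactly one of flow.Q and flow.F", call. = FALSE)
  if (has_F) defaults$flow <- list(F = NULL)   # swap the default Q for F
  cfg <- .merge_config(defaults, user)

  geom <- dimensionless_geometry(cfg$geometry$a, cfg$geometry$b,
                                 cfg$geometry$phi)
  if (!is.null(cfg$flow$Q)) {
    cfg$flow$F <- flow_rate_relation(Q = cfg$flow$Q, geom = geom)
  } else {
    cfg$flow$Q <- flow_rate_relation(F = cfg$flow$F, geom = geom)
  }
  if (cfg$model$Nb == 0 && cfg$model$Nt != 0)
    stop("config invalid: Nb = 0 requires Nt = 0", call. = FALSE)

  flat <- c(cfg$model, cfg$electro)
  for (nm in names(.param_ranges)) {
    v <- flat[[nm]]
    if (!is.null(v)) {
      rg <- .param_ranges[[nm]]
      if (v < rg[1] || v > rg[2])
        warning(sprintf("%s = %g lies outside the documented range %g-%g",
                        nm, v, rg[1], rg[2]), call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

# Build the solver inputs from a validated config.
.resolve_config <- function(cfg) {
  geom <- dimensionless_geometry(cfg$geometry$a, cfg$geometry$b,
                                 cfg$geometry$phi)
  m <- cfg$model
  p <- model_parameters(M = m$M, Gr = m$Gr, Nr = m$Nr, Rb = m$Rb, Rn = m$Rn,
                        Pr = m$Pr, Nb = m$Nb, Nt = m$Nt, Sc = m$Sc,
                        xi = m$xi, beta_t = m$beta, E = m$E, n_fit = m$n,
                        Pe = m$Pe, Omega = m$Omega, F = cfg$flow$F)
  shp <- cfg$nanofluid$shape
  shape <- if (is.list(shp)) {
    particle_shape("custom", s = shp$s, A1 = shp$A1, A2 = shp$A2)
  } else {
    particle_shape(shp)
  }
  list(p = p, geom = geom,
       mix = mixture_properties(cfg$nanofluid$phi1, shape),
       ek = electrokinetic_params(cfg$electro$kappa, cfg$electro$zeta1,
                                  cfg$electro$zeta2, cfg$electro$U_HS),
       opts = solver_options(tol = cfg$solver$tol,
                             max_nodes = cfg$solver$max_nodes,
                             n_init = cfg$solver$n_init,
                             continuation = cfg$solver$continuation),
       x = cfg$geometry$x)
}

.write_profile_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run a single-station solve from a configuration
#'
#' Solves the station problem, writes the profile CSV (columns `x, y, psi,
#' u_wave, u_lab, theta, sigma, chi`, 17-significant-digit `.`-decimal
#' floats, byte-stable across identical runs) and a JSON metadata file
#' carrying the fully resolved parameter set, wall scalars, solver
#' diagnostics and residuals.
#'
#' @param cfg A [load_config()] result (or a path to a config file).
#' @param profile,meta Output paths; default to the config's `output`
#'   section.
#' @return Invisibly, the `station_solution`.
#' @export
run_solve <- function(cfg, profile = NULL, meta = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  inp <- .resolve_config(cfg)
  sol <- solve_station(inp$x, inp$p, inp$geom, inp$mix, inp$ek, inp$opts)
  profile <- profile %||% cfg$output$profile
  meta <- meta %||% cfg$output$meta
  .write_profile_csv(as.data.frame(sol), profile)
  md <- list(
    config = unclass(cfg),
    resolved = list(params = unclass(inp$p),
                    mixture = unclass(inp$mix)[c("mu_r", "k_r", "sigma_r",
                                                 "rho_r", "rhobeta_r",
                                                 "rhocp_r")],
                    h1 = sol$h1, h2 = sol$h2),
    scalars = list(tau_s = shear_stress(sol), Nu = heat_flux_diagnostic(sol)),
    residuals = list(ode = sol$ode_residual, bc = sol$bc_residual),
    diagnostics = sol$diagnostics,
    software = list(package = "emhdflow",
                    version = as.character(utils::packageVersion("emhdflow"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(md, meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sol)
}

#' Run a parameter sweep from a configuration
#'
#' Uses the config's `sweep` section (`parameter`, `values`, `xs`), writes
#' the long-format profile table and the per-run wall-scalar table as CSVs,
#' and optionally one PNG panel per parameter value.
#'
#' @param cfg A [load_config()] result or config path.
#' @param profile,scalars Output CSV paths (default `sweep_profiles.csv`,
#'   `sweep_scalars.csv`).
#' @return Invisibly, the sweep table.
#' @export
run_sweep <- function(cfg, profile = "sweep_profiles.csv",
                      scalars = "sweep_scalars.csv") {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  inp <- .resolve_config(cfg)
  tab <- parameter_sweep(cfg$sweep$parameter, cfg$sweep$values,
                         p = inp$p, geom = inp$geom, ek = inp$ek,
                         phi1 = cfg$nanofluid$phi1,
                         shape = if (is.character(cfg$nanofluid$shape))
                           cfg$nanofluid$shape else "bricks",
                         xs = cfg$sweep$xs, opts = inp$opts)
  .write_profile_csv(tab, profile)
  .write_profile_csv(attr(tab, "scalars"), scalars)
  if (isTRUE(cfg$output$plots)) {
    grDevices::png(sub("\\.csv$", ".png", profile), width = 900, height = 600)
    plot_sweep(tab)
    grDevices::dev.off()
  }
  invisible(tab)
}

#' Print the default configuration as YAML
#'
#' @return Invisibly, the default config list.
#' @export
show_defaults <- function() {
  cat(yaml::as.yaml(default_config()))
  invisible(default_config())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
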