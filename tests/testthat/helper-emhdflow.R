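# Shared fixtures: parameter records for the analytically solvable limits.

# All forcing and coupling switched off: psi is a cubic, theta/sigma/chi are
# linear ramps.
trivial_params <- function(F = 1) {
  model_parameters(M = 0, Gr = 0, Nb = 0, Nt = 0, xi = 0, Pe = 0, F = F)
}

zero_electro <- function() electrokinetic_params(U_HS = 0)

pure_fluid <- function() mixture_properties(0)

# Exact cubic stream function for the symmetric trivial limit (half-width h):
# psi = c1*y + c3*y^3 with c3 = -(F + 2h)/(4h^3), c1 = -1 + 3(F + 2h)/(4h).
cubic_reference <- function(y, F = 1, h = 1.5) {
  c3 <- -(F + 2 * h) / (4 * h^3)
  c1 <- -1 + 3 * (F + 2 * h) / (4 * h)
  list(psi = c1 * y + c3 * y^3,
       dpsi = c1 + 3 * c3 * y^2,
       d2psi = 6 * c3 * y,
       d3psi = rep(6 * c3, length(y)))
}

midpoint_state <- function(sol, row) {
  unname(predict(sol, (sol$h1 + sol$h2) / 2)[row, 1])
}
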