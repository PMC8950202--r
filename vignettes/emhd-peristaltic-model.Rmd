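---
title: "Model and numerical methods in emhdflow"
author: "emhdflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and numerical methods in emhdflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emhdflow)
```

## The physical problem

`emhdflow` simulates the transport of a blood-based nanofluid laden with gold
nanoparticles through an asymmetric micro-channel whose flexible walls carry
travelling sinusoidal contraction waves (peristalsis). Two additional driving
mechanisms act along the channel: an axial electric field working on the
charged electric double layer (EDL) at the walls (electroosmosis), and a
transverse magnetic field whose Lorentz force opposes the flow. The fluid
also carries heat, a dilute nanoparticle phase and a population of gyrotactic
micro-swimmers, coupled through thermal buoyancy, Brownian/thermophoretic
diffusion, a temperature-activated consumption reaction and bioconvective
stratification.

In wave-frame coordinates moving with the wall wave, the walls sit at

$$h_1(x) = -1 - a\cos^2(\pi x + \phi), \qquad h_2(x) = 1 + b\cos^2(\pi x),$$

with amplitude ratios $a, b \ge 0$ and phase shift $\phi$; lengths are scaled
by the half-width transversally and by the wavelength axially. The gap never
closes ($h_2 - h_1 \ge 2$). The package evaluates these wall laws directly in
their dimensionless boundary-condition form; the amplitude ratios are
amplitude over half-width.

## Governing equations

In the lubrication limit (long wavelength, low Reynolds number) the 2-D
balance laws collapse to ordinary differential equations in the transverse
coordinate $y$ at each axial station $x$. Writing $\psi$ for the stream
function ($u = \psi'$ in the wave frame), $\theta$ for temperature, $\sigma$
for nanoparticle volume fraction and $\chi$ for motile-microorganism
density:

$$a_1 \psi'''' - a_2 M^2 \psi''
  + \mathrm{Gr}\,(a_3 \theta' - \mathrm{Nr}\,\sigma' - \mathrm{Rb}\,\chi')
  + \kappa^3 U_{HS}\,(A \sinh \kappa y - B \cosh \kappa y) = 0,$$

$$(a_4 + \mathrm{Rn\,Pr})\,\theta''
  + \mathrm{Nb\,Pr}\,\theta'\sigma' + \mathrm{Nt\,Pr}\,\theta'^2 = 0,$$

$$\sigma'' + \frac{\mathrm{Nt}}{\mathrm{Nb}}\theta''
  - \mathrm{Sc}\,\xi\,\sigma\,(1+\beta\theta)^n
    e^{-E/(1+\beta\theta)} = 0,$$

$$\chi'' - \mathrm{Pe}\,(\chi + \Omega)\,\sigma''
  - \mathrm{Pe}\,\chi'\sigma' = 0,$$

with boundary rows $\psi(h_1) = -F/2$, $\psi(h_2) = F/2$,
$\psi'(h_{1,2}) = -1$, $\theta,\sigma,\chi = 0$ at $h_1$ and $= 1$ at $h_2$.
The coefficients $a_1 = \mu_{nf}/\mu_f$, $a_2 = \sigma_{nf}/\sigma_f$,
$a_3 = (\rho\beta)_{nf}/(\rho\beta)_f$ and $a_4 = k_{nf}/k_f$ are the
effective-property ratios of the particle-laden mixture. The wave-frame flow
rate relates to the fixed-frame mean rate by $Q = F + 2 + (a+b)/2$.

The electroosmotic source is the third derivative of the Debye–Hückel EDL
potential $\varphi'' = \kappa^2 \varphi$, $\varphi(h_1) = \varsigma_1$,
$\varphi(h_2) = \varsigma_2$, scaled by the Helmholtz–Smoluchowski velocity:
identically $U_{HS}\kappa^2\varphi'(y)$. The coefficients $A, B$ of the
analytic solution $\varphi = A\cosh\kappa y - B\sinh\kappa y$ are evaluated
in scaled-exponential form so that thin double layers (large
$\kappa(h_2-h_1)$) cannot overflow; beyond $\kappa\,\max|h| \approx 700$ the
subsequent $\cosh$ evaluation itself would overflow and the package raises
an error advising a smaller $\kappa\cdot$width.

## Mixture model

The six property ratios follow standard dilute-suspension rules: a quadratic
shape-dependent viscosity law $\mu_r = 1 + A_1\varphi_1 + A_2\varphi_1^2$, a
Hamilton–Crosser-type conductivity with shape factor $s$ (bricks 3.72,
cylinders 4.82, platelets 5.72), a Maxwell-type electrical conductivity, and
volume-weighted mixture rules for $\rho$, $\rho\beta$ and $\rho c_p$. All
ratios are exactly 1 at $\varphi_1 = 0$. The built-in material constants are
the tabulated gold and blood values (`gold_properties()`,
`blood_properties()`). The shape registry is closed to the three tabulated
shapes plus a fully user-specified `custom` shape.

```{r mixture}
mixture_properties(0.05, particle_shape("bricks"))
```

## Parameters, defaults and units

All groups are dimensionless. Defaults are mid-range values of the intervals
over which the model is customarily exercised (`M` 0–6, `Gr` 0–6, `U_HS`
−3–9, `Rn` 0.1–0.7, `Nt` 1–9, `Nb` 0.1–0.9, `E` 1–4, `beta_t` 0–3, `Pe`
0–0.9, `kappa` 2–2.3, `zeta1` 1–1.6, `Rb`/`Nr` 1–1.6); the configuration
loader warns, without failing, when a value lies outside its interval.
Choices that the underlying model leaves open were fixed once as package
conventions and are not revisited:

* geometry `a = b = 0.5`, `phi = 0`, station `x = 0`, flow rate `Q = 3.5`
  (hence `F = 1`): a moderate symmetric occlusion with forward pumping;
* `zeta2 = 1` (only the left-wall zeta potential is customarily ranged);
* fitted rate exponent `n_fit = 0.5`, the midpoint of its admissible
  interval $(-1, 1)$;
* `Pr = 21`, the tabulated blood value. Deriving Pr from the other tabulated
  blood constants ($\mu_f c_{p,f}/k_f$) would instead give $\approx 2.92$;
  published blood Prandtl numbers vary this widely depending on the shear
  regime assumed. The solver therefore never derives Pr internally — it is
  an independent input, and the dimensional converter reports the derived
  value so users can see the discrepancy.

The dimensional converter (`nondimensionalize()`) maps laboratory
quantities (T in K, diffusivities in m²/s, B₀ in T, …) to these groups using
the standard definitions listed in its help page. Two groups are accepted
only in dimensionless form: the electroosmotic parameter $\kappa$ (half-width
over Debye length) and $U_{HS}$, because their laboratory definitions
involve electrokinetic material constants the package does not model. The
buoyancy ratio Nr uses the nanoparticle–fluid density difference and the
bioconvection Rayleigh number Rb the microorganism–fluid one, matching the
two buoyancy terms of the momentum balance. The Reynolds number and wave
number are computed but only reported as metadata: the lubrication-limit
core does not use them.

## Numerical method

No boundary-value solver for general first-order systems is available in the
package's dependency tier, so both discretisations are implemented here.

**Primary solver** (`solve_station()`): the system is written as ten coupled
first-order equations and discretised with 3-stage Lobatto IIIA collocation
(the Simpson/Hermite scheme, fourth order). The nonlinear algebraic system
is solved by damped Newton iteration with an analytic sparse Jacobian;
Newton is run to its roundoff floor (target $10^{-13}$ times the state
scale) because a looser algebraic tolerance would leave an artificial
$O(\mathrm{tol}/h)$ floor in the reported interior residual. The converged
solution carries a per-interval quintic Hermite interpolant (values and
slopes at the interval ends and collocation midpoint); the solver doubles
the mesh until the interpolant's residual $|S'(y) - f(S(y))|$ on a 4×-dense
check grid falls below `tol` (default $10^{-8}$, mesh capped at `max_nodes`
= 6401 with a warning). Grids ascend from $h_1$ to $h_2$; "left wall"
quantities are evaluated at the first grid point. The default 101-point
initial mesh is odd so the channel midpoint stays on the grid under
doubling.

**Cold start and continuation.** The initial guess is the exact solution of
the fully decoupled limit: a cubic stream function through the four $\psi$
boundary rows and linear $\theta, \sigma, \chi$ ramps. If Newton fails from
this guess, the forcing and nonlinearity parameters ($M^2$, Gr, $\xi$, Pe,
$U_{HS}$ and Nt, with Nb held fixed) are ramped jointly from zero in four
geometric steps ($\tfrac18, \tfrac14, \tfrac12, 1$). Nt is included in the
ramp because the $\mathrm{Nt\,Pr}\,\theta'^2$ term is the dominant
nonlinearity at the upper end of its range and a cold start from the
linear-temperature guess stalls there. Non-convergence after continuation is
an error that reports the last continuation fraction reached.

**Degenerate inputs.** `Nb = 0` is admitted only with `Nt = 0` (the
$\mathrm{Nt}/\mathrm{Nb}$ ratio is then taken as zero). Inside the solver
the Arrhenius denominator $1 + \beta\theta$ is clamped at $10^{-8}$ (with
the clamp's derivative zeroed); called directly, `ode_rhs()` instead raises
a domain error for non-positive denominators.

**Independent oracle** (`fd_oracle_solve()`): the scalar fourth/second-order
form is discretised with second-order central differences on a fixed uniform
grid (default 801 points), with two ghost points carrying the
stream-function slope conditions, and solved by the same damped Newton
strategy. Its residual has an irreducible roundoff floor
$\varepsilon\,\mu_r\,16/h^4$ from the five-point fourth difference;
stagnation below that floor counts as convergence. The ten-state profile is
reconstructed by numerical differentiation; $\psi'''$ uses seven-point
fourth-order stencils so the reported state is limited by the scheme's
$O(h^2)$ solution error rather than by an extra differentiation truncation.
The two discretisations share nothing but the model definition, so their
agreement (about $7\times10^{-5}$ max-abs over all ten states at the default
parameters, with the expected factor-4 error drop under grid halving for the
finite-difference side) is the package's main internal verification surface,
together with two closed forms: the trivial-limit cubic/linear solution and
the constant-coefficient momentum solution for $\mathrm{Gr} = 0$ (hyperbolic
basis plus a hyperbolic particular solution, switching to the secular
$y\cdot\{\cosh,\sinh\}$ form when $\kappa$ coincides with the Hartmann
wavenumber $M\sqrt{a_2/a_1}$ — which happens exactly at $M = 2$, $\kappa =
2$, $\varphi_1 = 0$).

```{r verify}
p <- model_parameters(Gr = 0, M = 2, Nt = 0, Nb = 0, xi = 0, Pe = 0)
sol <- solve_station(0, p, mix = mixture_properties(0))
cf <- closed_form_momentum(p, mixture_properties(0))
max(abs(sol$states["psi", ] - cf$psi(sol$grid)))
```

**Determinism.** There is no randomness anywhere: identical inputs give
bit-identical outputs on a fixed platform, and the profile CSVs are written
with 17 significant digits and `.` decimals so repeated runs are
byte-identical.

## Post-processing

The wave-frame velocity is $u = \psi'$; the lab-frame velocity is $u + 1$
(no-slip at the walls holds in the lab frame). The wall shear stress is
reported at the left wall, $\tau_s = \mu_r\,\psi''(h_1)$; a right-wall
variant exists for symmetry checks. Because the heat-transfer coefficient
admits several conventions, the exported diagnostic is defined by this
package as $\mathrm{Nu} = -(k_r + \mathrm{Rn\,Pr})\,\theta'(h_1)$ — the
conductive-plus-radiative wall flux scaled by the base-fluid conductivity —
and is documented as a repo-defined convention, not a literature value.
`parameter_sweep()` re-solves over a family of parameter values (including
particle shape and loading) and returns tidy long-format tables driving
figure-style plots; velocity output always carries both frames, with the
wave frame as the default plotted quantity.

## What the tests do and do not show

The test suite verifies: the analytic EDL potential against its ODE and
boundary conditions; the body-force/potential-gradient identity against
symbolic differentiation; all mixture ratios against 40-digit
arbitrary-precision reference values; the solver against the three closed
forms above; cross-discretisation agreement and the finite-difference
convergence order; boundary rows, frame transformation and stream-function
oddness on every converged run; and strict monotonicity of the midpoint
fields under the classical parameter responses (core velocity falls with M;
midpoint temperature falls with Rn and rises with Nt; midpoint volume
fraction rises with Nb; midpoint microorganism density falls with Pe; wall
shear rises with $\varsigma_1$). These are consistency checks of the model's
implementation — they do not validate the lubrication model itself against
measured blood flow, and no claim of clinical applicability is made.

Typical problem sizes: the default solve refines to ~1600 mesh points
(interior residual $3\times10^{-9}$); the oracle grids are 401/801 points;
the full suite solves a few dozen stations.

## Known limitations

* At the upper thermophoresis range (Nt near 9 with Pr = 21) the temperature
  equation develops a wall layer of width
  $\sim e^{-\mathrm{Nt\,Pr}/(k_r+\mathrm{Rn\,Pr})}$ — effectively a corner
  singularity that no practical mesh resolves. The solver then stops at the
  mesh cap with a warning and returns the outer solution; midpoint values
  and trend conclusions are unaffected, but boundary-layer quantities
  (e.g. $\theta'(h_1)$, hence Nu) are not converged there.
* Only one axial station is solved at a time; the lubrication limit treats
  stations independently, so no axial diffusion or entrance effects.
* No pressure-rise/pumping characteristics, no streamline-trapping analysis,
  no unsteady corrections, no induced magnetic field, and no nonlinear
  Poisson–Boltzmann double layer (the Debye–Hückel linearisation is built
  in).
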