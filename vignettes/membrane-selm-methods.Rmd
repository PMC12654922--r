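---
title: "Non-equilibrium membrane-protein simulation: model, discretization, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-equilibrium membrane-protein simulation: model, discretization, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memselm)
```

## The model

`memselm` simulates a single membrane protein coupled to two fluctuating
continuum fields on a flat, periodic membrane patch: the distribution
`q(x, t)` of a chemical species (concentration `c = c0 q`) and the membrane
temperature field `thetaC(x, t)`.  Two additional scalar temperatures track
the protein (`thetaP`) and the annulus of lipids around it (the
*interfacial region*, `thetaI`).  The full state is
`Y = [X, q, thetaP, thetaI, thetaC]`.

The over-damped protein obeys

    dX/dt = M F_X + H_thm,X,      M = I / gamma_p,

with `F_X = -grad Psi(X) - c0 * sum_m grad_X Phi(x_m; X) q_m dV`.  The
species performs drift-diffusion in its chemical potential `Phi(x; X)`,

    dq/dt = div(kappa grad q) + div((q / gamma) grad Phi),

with the local Stokes-Einstein diffusivity `kappa = thetaC / gamma` (the
drag `gamma` is fixed by the tabulated diffusivity at the baseline
temperature, `gamma = theta0 / kappa_bar`).  The membrane temperature obeys
a conduction equation with interfacial exchange, ambient relaxation and
*mechanical heating*; the protein and interface temperatures exchange heat
at rates `kappaPI` and `kappaCI(x; X) = kappaCI * eta_unit(x - X)`, a
kernel-shaped coupling footprint.  Every drift has a thermally consistent
fluctuation, constructed from the dissipative operator blocks described
below, so the mechanical and thermal parts of the system exchange energy
both ways.

Energy and entropy are explicit functionals (`total_energy()`,
`total_entropy()`): temperatures enter the energy linearly through the
specific heats and the entropy logarithmically; the species contributes the
mixing entropy `-c0 q ln q`.  Their gradients (`energy_gradient()`,
`entropy_gradient()`) are the analytic block forms and are tested against
finite differences.

### The coupling sign

With a positive interaction kernel the literal interaction energy
`V = int eta(x - X) c0 q dx` is *repulsive*; the positioning study's
narrative (protein and signaling species attract each other) requires the
opposite.  The package therefore implements `Phi(x; X) = s * eta(x - X)`
with default `s = -1` (attractive) and exposes `sign` in
`potential_kernel_coupling()`.  With this single sign choice the force on
the protein, the species drift in `grad Phi`, and the heating terms are all
mutually consistent, and the discrete energy balance closes exactly.

### Heating terms and exact discrete energy balance

The temperature-field heating produced by the species fluxes is implemented
in the form that makes the semi-discrete energy budget close identically:
per face, `c0 kappa_f (G Phi)(G q) + (c0 q_f / gamma) |G Phi|^2`, averaged
back to the two adjacent cells.  Together with the protein heating
`F M F / C_P`, every unit of potential energy released by the particle and
species fluxes reappears as heat; `deterministic_drift()` satisfies
`dE/dt = 0` to machine precision for a closed system (no ambient coupling),
and the time-discrete drift over 1000 steps stays below 1e-6 relative
(tested).  The quadratic heating term carries the face-averaged `q_f` — the
dissipated power per unit area of a drifting species is its number density
times the drag force squared over the drag — because that and only that
weight balances the advective energy flux of the discrete scheme.

A subtlety worth recording: with a *truncated* interaction kernel the
interaction energy is a discontinuous function of `X` (cells enter and
leave the support).  Each crossing causes an `O(exp(-r_cut^2 / 2 sigma0^2))`
jump in the tracked energy.  At the default `r_cut = 4 sigma0` on the study
grid this is a relative jump of order 1e-8 — far below the conservation
tolerance — but it is why the cutoff must not be taken much tighter.

## Spatial discretization

Fields live at the centers of square cells, `x_m = (m + 1/2) dx`, with
periodic wrap; fluxes live on faces, indexed by the cell on their negative
side.  `fv_gradient()` and `fv_divergence()` are the standard
central-difference pair, and on every grid the dense forms satisfy
`G = -t(D)` *exactly* — the adjointness that makes flux-form updates
conserve mass to machine precision and keeps the noise constructions
thermodynamically consistent.  Transport coefficients (`kappa`, `q`,
`thetaC`) are averaged to faces arithmetically; this choice preserves the
symmetry of the dissipative operators and is second-order accurate.

Particles couple to fields through truncated Gaussian kernels
(`kernel_spec()`), evaluated with the minimum-image convention; truncation
is at `4 sigma0` with no renormalization (mass defect `exp(-8) < 1e-3`,
documented rather than hidden).  A Peskin 4-point kernel is available for
interpolation; the three studies all use Gaussians.

## Fluctuations: dissipative blocks and factors

Each irreversible process contributes a symmetric positive semidefinite
block `K^(j)` and the corresponding noise is generated as
`h = sqrt(2 kB dt) R^(j) xi` with `R^(j) R^(j)^T = K^(j)`
(`dissipative_blocks()`, `sample_fluctuations()`).  The factors are
*divergence-form*: the species and conduction noises are white noise on
faces, scaled by `sqrt(thetaC_f q_f / (gamma c0 dV))` and
`sqrt(kappaCC / dV) thetaC_f / C_C` respectively, pushed through the
discrete divergence — `O(N)` generation, automatically mass-conserving per
draw, and with the `1/dV` weights that make the discrete
fluctuation-dissipation relation exact on the packed state vector.  The
scalar exchanges (protein-interface, interface-membrane per cell,
membrane-ambient) are rank-one antisymmetric differences with
geometric-mean temperature amplitudes `sqrt(kappa theta_a theta_b)`, which
reduce to the standard equilibrium form when the two temperatures agree.
On small grids each block exposes `dense_R()` and an independently
assembled `dense_K()`; `R R^T = K` holds to 1e-12 and the sampled
increment covariance matches `2 kB K dt` within Monte-Carlo error
(`increment_covariance_test()`).

## Time integration

`selm_step()` is a two-stage Euler-Heun scheme: predictor with drift and
noise coefficients at the current state, corrector averaging coefficients
at the current and predicted states, *reusing the same Wiener increments*.
This realizes the Stratonovich reading of the multiplicative noise, so no
explicit divergence drift is added.  Two properties are tested directly:
with state-independent noise amplitude one step reduces exactly to
Euler-Maruyama, and for the state-dependent exchange amplitude the scheme
matches (pathwise, against a paired oracle) an Ito-Euler reference that
carries the explicit Stratonovich correction `kB (dR/dY) : R`.  Note this
correction is *half* of the full divergence `kB div K = kB [(dR)R^T +
R div R^T]` that the thermodynamically exact (Klimontovich) form
prescribes; the residual is `O(kB)` relative to the drift and is orders of
magnitude below statistical resolution at the studies' `kB` of 1e-5 to
1e-3.  The equilibrium checks (Boltzmann position statistics,
free-diffusion MSD, below) confirm the integrator's stationary behavior at
those parameters.

Steps whose corrector produces a nonpositive temperature (or materially
negative `q`) are rejected and retried as two half-steps, up to five
halvings.  The conserved multiplicative `sqrt(q)` noise can legitimately
leave *tiny* negative values in essentially empty cells (the amplitude uses
`max(q, 0)`, the entropy a floor of 1e-12); rejection triggers only beyond
1e-3 of the field maximum, since rejecting sub-resolution negatives would
deadlock the step rather than fix it.

The compiled core (`run_selm()`) executes the identical scheme, drawing
its normals from R's RNG in the same canonical block order, and is pinned
to the R stepper draw-for-draw in the tests.  Identical seeds give
bit-identical trajectories.

## Numerical stability and what each study integrates

The two-stage explicit scheme is stable on the negative real axis only up
to `|lambda| dt < 2`.  Two of the tabulated parameter sets violate this at
their printed time steps: the positioning table's protein-interface
exchange has `kappaPI / C_P ~ 6.8e6` (so `|z| ~ 6.8e3` at `dt = 1e-3`),
and the sensing table's conduction has a diffusive eigenvalue
`~1.6e6` (so `|z| ~ 16` at `dt = 1e-5`).  Since implicit and exponential
integrators are out of scope, the scenario runners integrate exactly the
subsystems each study exercises:

* **Positioning** evolves `X` and `q` isothermally at `theta0`.  The
  thermal exchange rates (1e6 and up) exceed every mechanical rate by four
  or more orders of magnitude, so the temperatures are slaved to their
  equilibrium values; at `kB = 1e-5` their residual fluctuations have no
  measurable effect on the mechanical subsystem.
* **Sensing** evolves only `thetaC` (its table sets `kappaCI = 0` and the
  study has no mobile particle), at `dt = 1e-6` — the largest stable step,
  recorded as an explicit config override of the tabulated 1e-5.
* **Escape** is explicitly stable as tabulated (its stiffest rate,
  `kappa0 / C_C ~ 630`, gives `|z| ~ 1.9` at `dt = 3e-3`) and evolves the
  full state `[X, thetaP, thetaI, thetaC]`; the concentration field does
  not appear in that model.

The full coupled system remains available through `selm_model()`'s
`active` argument; the energy-conservation and covariance tests run it
with all five components live at stable parameters.

## Scenario defaults the studies leave open

* Positioning sweep: `kappa_bar` in {1.2e-3, 1.2e-2, 1.2e-1, 3.6e-1} at
  the tabulated drag — a 300-fold range spanning the "species much slower
  than the protein" and "species much faster" regimes; horizon `T_end =
  10` (the scaled position plateaus by `t ~ 5` at both extremes).  On the
  periodic domain the source at `(1.5, 1.5)` is nearest the protein at the
  origin *through the wrap* (separation 0.707), so the scaled position `y`
  uses minimum-image displacements: `y = 0` at the start, `y = 1` at the
  source, regardless of the path taken.
* Sensing: one sensor per cell column at mid-height; amplitudes
  {0.01, 0.1, 1.0}; the filtered signal is time-averaged over the second
  half of a `T = 5e-4` run.  Detection is judged against the replicate
  standard deviation (the study's error bars): resolved means the fitted
  modulation amplitude exceeds twice that noise, obscured means it falls
  below it.
* Escape: staggered 3x3 well lattice with spacing 2/3 (which places a
  well center at the tabulated start `(5/3, 1)`); heating width `sigma3 =
  0.3` and escape radius `r0 = 0.4` (just beyond the well width, inside
  the lattice spacing); heating centered on the start well; sustained
  heating (ambient relaxation toward the heated profile), with an
  initial-condition-only mode available; horizon `T_max = 90` with
  censored replicates reported as such; heating strengths {0, 2, 5, 10}.
  At the tabulated well strength the cold baseline's mean escape time is
  far beyond any tractable horizon, so baseline summaries are lower
  bounds — which only understates the contrast the study demonstrates.
* Replicates: 50 per condition by default; every replicate seed derives
  deterministically from the scenario seed.
* The Arrhenius check (log mean escape linear in well depth at uniform
  temperature) uses a *single isolated* well, depths of 4-6 `kB theta0`,
  and a lighter drag (`gamma_p = 0.01`) so the means stay within a
  tractable horizon.  On the staggered lattice the neighboring wells pull
  on the `r0 = 0.4` escape ring with a force that also scales with the
  well strength, which masks the barrier effect being measured; the
  isolated-well means additionally agree with the closed-form radial
  first-passage-time integral, an independent oracle.

## Validation protocol

`transfer_operator_convergence()` evolves the deterministic conduction
operator from a single sinusoidal mode on dyadically refined grids and fits
the log-log slope of the maximum-norm error against the *continuum*
decaying sinusoid; the observed order is 2 (slope band 1.85-2.15).  The
comparison deliberately targets the continuum solution — against the
semi-discrete one the error would collapse to the temporal order and the
spatial statement would be empty.  `increment_covariance_test()` freezes a
fully-populated 4x4 state and compares the empirical covariance of 1e4
integrator increments entrywise to `2 kB K dt` with Gaussian sampling-error
z-scores (limit 5).  `equilibrium_suite()` checks equipartition in a
harmonic well (variance within 3 standard errors over 1e4 decorrelated
samples), the free-diffusion MSD slope (within 5% over 1e4 paths), and the
closed-system energy drift (below 1e-6 relative over 1e3 steps).

Problem sizes (4x4 covariance states, 16-64 grids for convergence, 50
replicates per scenario condition, horizons of order 10-100 time units)
are chosen so the full validation and scenario battery completes in
minutes on one CPU while every statistical check retains the resolution
its tolerance requires.

## What the synthetic inputs do and do not emulate

All inputs are generated programmatically: Gaussian concentration blobs,
sinusoidal and localized-heating temperature profiles, staggered well
lattices, and band-limited random fields for operator tests.  They
reproduce the studies' initial and boundary conditions exactly, but they
are not real membranes: the geometry is flat and static (no undulations or
curvature coupling), hydrodynamic interactions are reduced to a scalar
drag (no Saffman-Delbruck mobility), the species is dilute and
non-reactive, and sensor readout stops at a first-order filter.  Passing
tests therefore certify the *method* — discretization, fluctuation
generation, integration, and the studies' qualitative mechanisms — not
quantitative agreement with any experimental membrane system.

## Known limitations

* The explicit integrator restricts usable time steps at stiff parameter
  sets (see above); there is no implicit or exponential fallback by
  design.
* The Stratonovich scheme realizes half of the full `kB div K` drift; at
  `kB` of order 1 this would bias stationary statistics, though all
  shipped studies operate at `kB <= 1e-3`.
* Truncated kernels make forces discontinuous at the cutoff at the
  `exp(-8)` level.
* Escape-time summaries at strong wells are censored-mean lower bounds,
  not Kramers-rate estimates.
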