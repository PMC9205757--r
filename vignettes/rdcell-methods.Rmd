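---
title: "Methods: hybrid continuum-discrete reaction-diffusion simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid continuum-discrete reaction-diffusion simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcell)
```

## The model

`rdcell` simulates systems of the form

$$\frac{\partial u_s}{\partial t} - D_s(\mathbf{x}) \nabla^2 u_s =
R_s(u_1, \dots, u_n), \qquad s = 1, \dots, n,$$

on a two-dimensional rectangular domain, for an arbitrary number of
chemical species $u_s$, coupled to a population of point-like cell agents.
Each cell runs its own intracellular reaction network (an ODE system),
exchanges chemicals with the bulk at its location through *transport*
reactions (mass crosses the membrane) and *membrane* reactions (a shared
rate advances one reaction on each side of the membrane, nothing crosses),
divides when a designated species reaches a threshold, and dies when one
falls below a minimum.  The domain can be partitioned into labelled
subdomains, each carrying its own diffusion coefficients and bulk reaction
system, so that e.g. a biofilm region and the surrounding medium can use
different chemistry.

Each time step executes four phases in a fixed order: (1) intracellular
reaction networks, (2) the bulk reaction-diffusion update, (3)
bulk-to-cell coupling through transport and membrane reactions, and (4)
cell rules (death, then threshold division) followed by spring-force
position updates.

## Spatial discretization

The domain is a structured grid of squares of side $h$, each split into two
linear (P1) triangles along its lower-left to upper-right diagonal.  The
stiffness operator per species uses the exact linear-basis gradient
integrals with the element diffusivity taken from the element's subdomain
(the label of its lower-left node); the mass operator is lumped, giving
each node the *nodal volume share* — one third of the area of its incident
triangles.  The shares partition the domain area exactly, and double as the
"cell volume" in bulk-cell coupling: a nodal concentration times the share
is an amount.

Reactions are evaluated *at the nodes* on the lumped mass rather than
interpolated to interior Gauss points.  At linear-basis order the two
discretizations agree on smooth fields, and the nodal form makes the
conservation properties exact and easy to audit; the test suite verifies
mass conservation of diffusion-only runs to $10^{-10}$ relative over
$10^3$ steps.  Quadrature-point interpolation is therefore not carried
around; cell agents bind to their *nearest mesh node* (ties broken toward
the lowest node index), which is the consistent injection point for a
lumped-mass scheme.

Subdomain labels come from a topology matrix that is stretched to the mesh
extent: a node takes the label of the closed topology cell containing it,
with boundary ties resolved toward the lower-left cell.  The first row of
the topology file is the top of the domain, as a person reads the matrix.

## Time stepping

The default scheme is IMEX with a fixed step `dt`:

1. the reaction source at every node is advanced by one explicit
   fourth-order Runge-Kutta step of the local ODE system;
2. diffusion is advanced implicitly (backward Euler), species by species,
   solving $(M + \Delta t\, K_s)\, u^{n+1} = M u^* + \Delta t\, b_s$ with a
   sparse Cholesky factorization computed once per run.

Implicit diffusion is unconditionally stable, so the step size is limited
only by the reaction kinetics and by accuracy; the default `dt = 0.01`
(and `h = 1`) is used where a model does not specify its own.  The
implicit step satisfies a discrete maximum principle, which the suite
property-tests.  Intracellular networks use the same RK4 scheme.

**Non-negativity guard.** Explicit stepping of stiff kinetics can
undershoot zero.  RK4 stage inputs are floored at zero before evaluation
and the step result is clipped at zero; coupling updates that would drive
a concentration negative are instead rescaled so the limiting species
stops exactly at zero, which preserves the exchange balance.  Rate
evaluation itself rejects negative concentrations as an invalid state.

**Boundary conditions** are per species: zero-flux Neumann is natural; a
nonzero Neumann flux enters each boundary node weighted by half the length
of its adjacent boundary edges (so total influx equals flux times
perimeter exactly); Dirichlet values are pinned by symmetric elimination
(rows and columns zeroed, diagonal set to one), keeping the system
symmetric positive definite; periodic conditions identify right-to-left
and top-to-bottom edge nodes before factorization.

## The reaction grammar

Reaction files carry one reaction per line:

```
rate-law ":" equation ";" name "=" value {"," name "=" value}
```

with `->` / `<->` arrows, integer stoichiometric coefficients, `+`
between terms, and an empty side denoting the null species.  Four rate
laws are built in — zeroth order (`k`), irreversible mass action (`k`),
reversible mass action (`k_f`, `k_r`; an empty side contributes a factor
1, so `<-> U` gives the production/removal rate $k_f - k_r U$), and
Michaelis-Menten (`k_cat`, `K_M`, with the enzyme species named by a
token-valued `enzyme =` parameter) — and `register_rate_law()` accepts
user-defined laws.  Spectator species (named by repeatable `spectator =`
entries) multiply mass-action rates linearly (exponent 1).  Transport
lines read their left-hand side in the bulk namespace and their right-hand
side in the cell namespace; membrane lines carry two equations separated
by `|` (outer, bulk-facing; inner, cell-facing) whose shared rate is
computed over the union of outer and inner reactants.  Chemical property
fields beyond name and diffusivity (mass, valence, Gibbs formation
energy) are stored and exposed but do not modify rates in this version.

## Cell agents

Cells are strictly point-like.  Division triggers when any thresholded
species reaches its maximum; the parent keeps a fraction $\rho$ (default
0.5) of every species and the daughter the rest, so totals are conserved
exactly — division has no other effect on the state.  The daughter is
placed one mesh spacing away at a uniformly random angle.  Death removes a
cell when any thresholded species falls below its minimum; death is
checked before division within phase 4.  Motility is passive: pairwise
Hookean springs with rest length half the interaction cutoff, integrated
with overdamped first-order dynamics (unit drag), positions clamped to
the domain.  Several cells may bind one node; their couplings are applied
sequentially in cell-id order within a step, a documented convention since
no other ordering is implied by the physics.  Cell-side state is treated
as an amount-like concentration in a unit cell volume; the bulk-side
update divides by the nodal volume share, making balanced exchanges
conserve total amount to round-off (tested to $10^{-10}$ over $10^3$
coupled steps).

## Verification analytics

* **Traveling waves.** For the logistic-growth invasion model with unit
  parameters the minimum front speed is $c_{\min} = 2\sqrt{rD} = 2$.
  `measure_wave_speed()` tracks the mid-height ($\kappa/2$) crossing on
  the mid-domain slice by linear interpolation and fits the speed over the
  last half of *valid* samples — those whose front lies at least two grid
  cells from either end.  The validity filter matters on reduced domains:
  once the front reaches the far boundary the crossing disappears and late
  samples would otherwise poison the fit.  `fisher_analytic_profile()`
  provides the asymptotic front shape, order 0 the logistic profile and
  order 1 the $c^{-2}$ correction term.
* **Convergence scores.** `l2_convergence_score()` is the RMS difference
  of two profiles, capped at 0.5, with failed runs reported as 1.0.
  `fisher_convergence_grid()` sweeps step sizes and scores each run's
  final front against the order-1 analytic profile after aligning
  mid-heights.  The default ladder (`h` in 4, 2, 0.5; `dt` in 0.2, 0.05,
  0.01) spans a decade because the comparison has a floor: the order-1
  expansion truncates at $O(c^{-4})$, so once the numerical error drops
  to roughly $2\times10^{-3}$ RMS further refinement cannot reduce the
  score, and a ladder confined to that floor has no meaningful ordering.
* **Linear stability.** For the two-species autocatalytic network with
  rates $k_1, k_{-1}, k_2, k_3$ the steady state is
  $U^* = (k_1+k_2)/k_{-1}$, $V^* = k_2/(k_3 U^{*2})$.  The Hopf locus in
  $k_1$ solves $\mathrm{tr}\,J = -k_{-1} + 2k_2/U - k_3U^2 = 0$, which is
  strictly decreasing in $U$, so `hopf_point()` brackets the unique
  positive root and bisects to $10^{-10}$; the determinant
  $k_{-1}k_3U^{*2}$ is always positive, so a positive $k_1$ root is a
  genuine Hopf point.  `turing_band()` returns the wavenumber-squared
  interval of growing modes from the dispersion quadratic
  $D_UD_Vq^4 - (D_Vf_U + D_Ug_V)q^2 + \det J = 0$, empty whenever the
  undiffused state is not stable.  A brute-force eigenvalue scan over a
  $10^{-4}$ grid in $k_1$ cross-checks the bisection in the tests.

## The bundled exemplars

The exemplar generator writes complete model directories; these are the
package's synthetic data and define its study conditions.

* `fisher_kpp`: one species, $D = r = \kappa = 1$, a unit strip of
  invader at the left edge, zero-flux boundaries.  The travel direction is
  taken as the long axis (width 100, height 10): a front moving at speed
  2 needs that much room over the simulated interval.  The logistic
  source is encoded as the exact mass-action pair `U -> 2U` (rate $r$)
  and `2U -> U` (rate $r/\kappa$).
* `schnakenberg_oscillation` / `schnakenberg_pattern`: the two classical
  regimes of the autocatalytic two-species network on a 100x100 square,
  zero-flux boundaries, initial conditions perturbed per node by
  Uniform(-1, 1) from a seeded generator and floored at zero.  The
  oscillatory set ($k_1=0.5$, $k_{-1}=2.2$, $k_2=1.5$, $k_3=1$,
  $D_U=D_V=0.5$, start (0.91, 1.67)) sits on the unstable side of the
  Hopf point at $k_1 = 0.61$; the patterning set ($k_1=0.1$,
  $k_{-1}=1$, $k_2=0.9$, $k_3=1$, $D_U=1$, $D_V=40$, start (1, 1)) is
  stable without diffusion and Turing-unstable with it, with an unstable
  band $q^2 \in (0.034, 0.741)$.
* `cooperator_cheater`: two cell types seeded at the center of a bulk
  carrying enzyme, substrate, enzyme-substrate complex and oxygen.  All
  rate constants stated by the source model are 1, with the cheater's
  enzyme-production rate set to zero.  The remaining values are package
  defaults chosen once as plausible for a micron-scale microbial toy
  model and documented here: domain 20x20 ($h=1$); diffusivities 0.1 for
  the protein-sized species (enzyme and complex) and 1 for the small
  molecules (substrate, oxygen); boundary influx 0.05 for substrate and
  oxygen (continual replenishment); initial bulk substrate 0.5 and oxygen
  1; intracellular pools NAD = ADP = 1, ATP = 0.5, biomass 0.5; the
  cooperator starts with one unit of internal enzyme so secretion can
  bootstrap scavenging; biomass division threshold 1 with death threshold
  0 (inert); spring cutoff 1.5, stiffness 1, seed cells two mesh units
  apart.  The written fixture keeps the long end time of 10000 of the
  original scenario; tests and the acceptance analysis run a scaled-down
  window ($t_{\mathrm{end}} = 40$, `dt = 0.02`), which is enough for the
  qualitative contrasts (enzyme localized around cooperators, cooperator
  biomass at or above cheater biomass).

What the exemplars do *not* emulate: real microbial parameter magnitudes
(all rates are unit-scaled), stochastic kinetics, cell geometry and
volume exclusion beyond the spring force, active motility, juxtacrine
transport, and three-dimensional geometry.  Passing tests on these
fixtures demonstrates correctness of the numerics and the couplings, not
biological calibration.

## Problem sizes used by the tests

The suite runs reduced versions of each study: the traveling-wave run on
60x10 at $h = 0.5$, `dt = 0.01` to $t = 40$ (2541 nodes); the patterning
run on 50x50 at $h = 1$, `dt = 0.05` to $t = 200$; the oscillation check
as a well-mixed integration to $t = 500$ at `dt = 0.02`; the convergence
sweep on 60x10 to $t = 20$ over the 3x3 ladder above; the cell exemplar
to $t = 40$.  These sizes keep the whole suite within a few minutes while
leaving each phenomenon clearly resolved.

## Known limitations

* Strictly two-dimensional, structured meshes only.
* The reaction substep is explicit: kinetics much stiffer than the
  chosen `dt` require a smaller step (no adaptivity).
* One boundary-condition spec per species applies to the whole boundary;
  per-edge conditions are not expressible.
* Turing patterns of the bundled parameter set saturate at a spatial
  standard deviation just under 1 (the field ranges roughly 0.14-3.7
  around $U^* = 1$), and the pattern keeps rearranging slowly for a long
  time after onset; analyses that expect the final amplitude to dwarf the
  Uniform(-1, 1) seeding noise, or the field to be numerically frozen by
  $t = 200$, will not see that here.
* Thermodynamic rate corrections from the stored Gibbs energies, and
  stochastic (Gillespie) kinetics, are out of scope.
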