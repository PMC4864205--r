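---
title: "Lattice Boltzmann hemodynamics in a bifurcation aneurysm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice Boltzmann hemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hemolbm` simulates laminar blood flow in a carotid-style bifurcation with
an aneurysm sac, using the lattice Boltzmann method (LBM) on the D3Q19
velocity set. This vignette describes the models, the tunable parameters,
the numerical choices, and what the package's validation exercises do and do
not demonstrate.

## The lattice Boltzmann model

Instead of discretizing the Navier-Stokes equations, LBM evolves particle
distribution functions $f_i(\mathbf{x}, t)$ along 19 discrete velocities
$\mathbf{e}_i$ (one rest, six axis, twelve face-diagonal) on a regular grid:

$$f_i(\mathbf{x} + \mathbf{e}_i, t + 1) = f_i(\mathbf{x}, t) +
  \Omega_i[f](\mathbf{x}, t),$$

where the right-hand side is collision and the left-hand shift is streaming.
Density and momentum are moments of $f$: $\rho = \sum_i f_i$,
$\rho\mathbf{u} = \sum_i f_i \mathbf{e}_i$. In the low-Mach limit the scheme
recovers incompressible Navier-Stokes dynamics with kinematic viscosity
$\nu_{LB} = c_s^2(\tau - 1/2)$, $c_s^2 = 1/3$, so stability requires
$\tau > 1/2$.

Four collision operators are implemented, selected by name:

* **`bgk`** — single relaxation toward the quadratic Maxwell-Boltzmann
  expansion, $\Omega = (f^{eq} - f)/\tau$.
* **`incompressible`** — the equilibrium's velocity terms are multiplied by
  a constant reference density $\rho_0$ rather than the local $\rho$, which
  removes a division and reduces compressibility error; the matching
  velocity definition is momentum$/\rho_0$.
* **`regularized`** — before relaxing, the non-equilibrium part is replaced
  by its projection on the second-moment (stress) space,
  $\hat f^{neq}_i = \frac{w_i}{2c_s^4} Q_{i\alpha\beta}
  \Pi^{neq}_{\alpha\beta}$ with $Q_{i\alpha\beta} = e_{i\alpha}e_{i\beta} -
  c_s^2\delta_{\alpha\beta}$, discarding non-hydrodynamic ("ghost") content
  that destabilizes low-$\tau$ runs.
* **`mrt`** — collision in the space of 19 orthogonal velocity moments
  (density, energy, momentum and energy fluxes, five shear moments with
  fourth-order partners, three third-order ghosts), each relaxed at its own
  rate. The five shear-moment rates default to $1/\tau$ so all four
  operators share one viscosity; ghost and energy moments default to rate 1.
  With every rate at $1/\tau$ the operator reduces to BGK identically — a
  property the tests assert to round-off.

Because no transformation matrix convention is universal, the package
constructs the standard orthogonal polynomial basis explicitly
(`mrt_matrix()`), and computes equilibrium moments as $M f^{eq}$ rather than
from closed-form moment equilibria; this guarantees the BGK-degeneracy
property by construction. The ghost-moment rates are a documented default,
not a calibrated value: steady laminar results are insensitive to them, and
the cross-model pipe comparison verifies this operationally.

### Forcing

Body forces (gravity-like driving and the multiphase interaction force) use
the classic velocity-shift: the equilibrium inside the collision is
evaluated at $\mathbf{u} + \tau\mathbf{F}/\rho$, and the physically reported
momentum is $\rho\mathbf{u} + \mathbf{F}/2$. Applied literally inside MRT or
the regularized projection the shift is inert — the conserved-moment rates
(MRT) and the zero first moment of the stress projection (regularized) stop
the force from ever entering the momentum balance. The package therefore
applies forcing as the explicit source

$$S_i = \tfrac{1}{\tau}\left[f_i^{eq}(\rho, \mathbf{u} + \tau\mathbf{F}/\rho)
 - f_i^{eq}(\rho, \mathbf{u})\right],$$

which is algebraically identical to the velocity shift for BGK and injects
the same momentum $\mathbf{F}$ per step under every operator.

## Units

All user-facing configuration is SI; the lattice system is internal.
`unit_system(dx, dt, rho_phys, nu_phys)` fixes the scalings
$u_{LB} = u\,\delta t/\delta x$, $\nu_{LB} = \nu\,\delta t/\delta x^2$,
$\tau = 3\nu_{LB} + 1/2$, and pressure/stress convert with
$\rho_{phys}(\delta x/\delta t)^2$. At the blood-flow reference point
($\delta x = 1.56563\times10^{-4}$ m, $\delta t = 5\times10^{-5}$ s,
$\nu = 3.7037\times10^{-6}$ m$^2$/s, $\rho = 1060$ kg/m$^3$,
$\bar u = 0.1$ m/s) this yields $u_{LB} = 0.0319361$,
$\nu_{LB} = 0.0075549$, $\tau = 0.52266$, and an inlet Reynolds number
$Re = \bar u D_{inlet}/\nu \approx 170$ for $D_{inlet} = 0.63$ cm. Note the
lattice Reynolds number reproduces 170 when the inlet length scale is the
inlet diameter in nodes ($\approx 40.2$ at this $\delta x$); a resolution
figure of $\approx 19.4$ nodes does not close this identity and is treated
as informational only.

## Geometry

`bifurcation_spec()` parameterizes the vessel: inlet trunk (default
diameter 0.63 cm) splitting at an apex into two branches (0.45 and 0.3 cm)
at $+40°$ and $-60°$ from the trunk axis, with a spherical sac (default
radius 0.35 cm) attached laterally above the junction, its neck opening to
the trunk/first-branch corner. Branch angles, segment lengths and sac
placement are free parameters with documented defaults — the published
description fixes only the three diameters, so the generator reproduces the
qualitative shape, not an exact CAD surface.

Voxelization flags a node fluid iff its center lies inside the solid
(staircase boundaries, no partial volumes), which is precisely the regular
Cartesian meshing LBM is normally used with. The trunk base lies in the
$x = 0$ plane and both branches are truncated by the far $x$ face, so the
inlet and the two outlet discs are planar and axis-aligned. Fluid pockets
not reachable from the inlet are removed by flood fill. Triangulated
surfaces (ASCII or binary STL) can be voxelized instead via even-odd ray
casting, and any voxelized geometry can be exported back to STL as its
staircase surface for visual checks.

## Boundary conditions

* **Walls** — halfway bounce-back: a population that would stream into a
  solid node is returned, reversed, to its source node, placing the no-slip
  plane half a link beyond the last fluid node. Closed domains conserve
  mass to round-off per step (asserted in the tests).
* **Inlet** — a laminar parabolic profile $u(r) = 2\bar u[1 - (r/R)^2]$
  over the inlet disc (centreline speed twice the average). Inlet nodes are
  rebuilt as the equilibrium at the prescribed velocity and the density
  extrapolated from the interior neighbour, plus the neighbour's
  non-equilibrium part. The density must come from the fluid side: with a
  purely local density the boundary admits a spurious zero-flow steady
  state in which the density drifts until the prescribed-velocity
  equilibrium mimics a rest state on the few link populations that actually
  cross into the fluid. Inlet nodes flagged outside the disc radius are
  held at zero velocity (wall behaviour) with a one-time warning.
* **Outlets** — zero gauge pressure: density pinned to $\rho_{ref} = 1$
  with the velocity extrapolated from the interior neighbour
  (equilibrium + copied non-equilibrium). Both outlets share one
  $\rho_{ref}$, so the flow split between branches is an emergent result.
  All reported pressures are relative to the outlets.

The driver initializes at equilibrium ($\rho = 1$, $\mathbf{u} = 0$) and
ramps the inlet linearly over a configurable warm-up (default 1000 steps)
to avoid startup pressure shocks. Convergence is declared when the relative
L2 change of the velocity field across a 100-step window falls below the
tolerance (default $10^{-6}$); the steady pipe tests additionally verify
that the converged state is independent of initialization.

## Shan-Chen multiphase model

Single-component pseudopotential interaction with effective mass
$\psi(\rho) = \rho_0[1 - e^{-\rho/\rho_0}]$ and nearest-neighbour force

$$\mathbf{F}(\mathbf{x}) = -G\,\psi(\mathbf{x}) \sum_i w_i\,
  \psi(\mathbf{x} + \mathbf{e}_i)\,\mathbf{e}_i .$$

The published sign conventions for $G$ conflict (a leading minus sign in
the force next to "positive means attraction"), so the package fixes the
behavioural contract instead: with the convention above the bulk pressure
is $p = c_s^2\rho + \tfrac12 c_s^2 G \psi^2$, phase separation requires
$G < -4$ (at $\rho_0 = 1$), and the tests assert that exactly one sign of
$G$ separates. Lattice-weighted neighbour sums are the default (the
unweighted "corral" sum is available but anisotropic at fourth order).
Solid neighbours contribute a configurable wall $\psi$ (default 0). Mass is
conserved exactly; momentum is conserved globally (not locally) in periodic
domains, and both are asserted from per-step budget traces. Flat-interface
coexistence densities are validated against an independent brute-force 1D
(D1Q3) lattice equilibrium: for strictly one-dimensional states the D3Q19
dynamics projects exactly onto a three-velocity lattice with the same
$c_s^2$ and a force-stencil coefficient of $1/6$, making the small
stand-alone 1D code a genuine oracle.

## Post-processing

* **Pressure** — $p = c_s^2(\rho - \rho_{ref})$ converted to Pa.
* **Wall shear stress** — at each wall-adjacent fluid node the deviatoric
  stress is recovered locally from the non-equilibrium populations,
  $\sigma_{\alpha\beta} = (1 - \frac{1}{2\tau})\sum_i f_i^{neq}
  e_{i\alpha} e_{i\beta}$, the traction $\mathbf{t} = \sigma\mathbf{n}$ is
  projected tangentially, and the magnitude is converted to Pa. This
  local-moment route (rather than velocity finite differences) is exact at
  the Chapman-Enskog level and needs no interpolation stencils near
  staircase walls. Normals default to the gradient of the box-smoothed
  solid indicator; parametric geometries may supply analytic normals, which
  removes the dominant (normal-direction) error of staircase surfaces.
  Wall cells with an undefined normal (isolated voxels) are excluded and
  counted.
* **Probes and planes** — trilinear interpolation at physical coordinates;
  probes whose eight enclosing nodes are not all open are rejected by
  index. Axis-aligned plane slices return density, speed and pressure.
* **Comparisons** — per-point percentage difference $100(a-b)/b$ (zero
  references flagged and excluded from summaries) and absolute change
  $b - a$.
* **WSS distributions** — percentage-of-cells histograms over a fixed
  range (percentages sum to 100 over the covered range), quartiles by
  linear interpolation between order statistics, and $1.5\,$IQR outliers —
  the standard box-plot conventions.
* **Threshold views** — a mask of nodes whose physical speed exceeds a
  cutoff (default 0.05 m/s), the rendering that exposes near-stagnant
  aneurysm interiors.

## Validation problem sizes and choices

The full-scale aneurysm run (350 cells across a 5.6 cm reference length,
a ${\sim}4\times10^7$-node bounding grid) is a cluster-scale computation;
the package's correctness case rests on analytic flows plus a
reduced-scale aneurysm run:

* **Poiseuille pipe** (all four operators): a body-force-driven periodic
  staircase cylinder of diameter $\approx 48$ nodes at $\tau = 0.8$, mean
  speed targeted at the reference lattice velocity 0.0319361. The tests
  require the velocity profile within 2% relative L2 of the parabola and
  mean wall shear within 10% of $4\mu\bar u/R$, and all model pairs within
  1% of each other. $\tau = 0.8$ is chosen because halfway bounce-back
  places the wall accurately there; at $\tau \to 1/2$ the effective wall
  moves measurably inside the halfway plane (a known artifact of
  bounce-back, discussed below).
* **Shear-wave decay** (BGK and MRT): a periodic sinusoidal shear wave
  whose amplitude must decay at $\nu k^2$ within 1%, fitted between two run
  lengths to skip the initial non-equilibrium transient.
* **Hagen-Poiseuille pressure drop**: velocity-inlet/pressure-outlet pipe,
  radius 14.2 nodes at $\bar u_{LB} = 0.01$, within 5%. The radius and
  speed keep the two known error sources — compressibility along the pipe
  and the staircase effective-radius offset — jointly inside the bound.
* **Reduced-scale aneurysm**: 80 cells across the reference length
  (inlet diameter $\approx 9$ nodes), MRT at the reference lattice
  viscosity 0.0075549 ($\tau = 0.52266$), inlet average pinned to 0.1 m/s
  by the time step, giving $Re \approx 96$. A coarse grid cannot carry
  $Re = 170$ without violating the low-Mach constraint, so this run is a
  reduced-Reynolds analog; the asserted features are topological: the wall
  pressure maximum within 1.5 inlet diameters of the apex, stagnant flow
  (under 0.05 m/s) dominating the sac interior, WSS maximal near the
  bifurcation and minimal on the sac wall. MRT is used here for its
  stability margin at low $\tau$ — the same motivation the regularized and
  moment-space operators have in the literature. At substantially lower
  Reynolds number ($\approx 36$) the viscous pressure drop overwhelms the
  apex stagnation spot and the wall-pressure maximum migrates to the inlet,
  so the topology assertions are genuinely Reynolds-sensitive.

What passing these tests shows: the solver reproduces analytic
incompressible laminar solutions, all four operators agree where they
should, units and observables are consistent, and the qualitative
hemodynamic picture of a bifurcation aneurysm emerges at reduced scale.
What it does not show: grid convergence at the published resolution,
pulsatile or transitional flow physics, or patient-specific accuracy.

## Known limitations

* Staircase walls with halfway bounce-back have a $\tau$-dependent
  effective wall position; near $\tau = 1/2$ the wall sits a fraction of a
  link inside the halfway plane, biasing narrow-tube flows by a few
  percent. Interpolated (partial-link) boundaries would remove this but
  are out of scope.
* WSS is evaluated at wall-adjacent node centers, roughly half a link to a
  link inside the true wall, so pipe wall shear is systematically a few
  percent low; smoothed-indicator normals add a comparable error on
  staircase surfaces unless analytic normals are supplied.
* The quasi-compressible pressure field carries $O(Ma^2)$ error; all
  validation fixtures keep lattice speeds at or below 0.08.
* Single-phase, Newtonian, rigid-wall, steady-inlet flow only; the
  Shan-Chen module is single-component with velocity-shift forcing (no
  exact-difference or Guo schemes, no multicomponent interaction matrix).
* The reduced-scale aneurysm run is a laminar analog at $Re \approx 96$,
  not a reproduction of the published $Re \approx 170$ fields.
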