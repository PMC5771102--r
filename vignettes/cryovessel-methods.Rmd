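---
title: "Simulating cryosurgical freezing near a bifurcated artery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cryosurgical freezing near a bifurcated artery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryovessel)
```

## The problem

Cryosurgery destroys diseased tissue by freezing it with inserted cryoprobes
whose active tips run at liquid-nitrogen temperature (−196 °C). Large blood
vessels (above ~0.5 mm) are thermally significant: warm blood flowing past the
frozen region continuously reheats it, deforms the growing "iceball", can keep
parts of the target above lethal temperature, and — from the opposite
perspective — protects the vessel wall itself from freezing injury. Near an
arterial *bifurcation* the flow field, and hence the convective heating, is
strongly inhomogeneous.

`cryovessel` simulates this situation: a symmetric arterial bifurcation
embedded along the axis of a cylinder of perfused tissue, one or several
cryoprobes inserted horizontally near the bifurcation, steady laminar blood
flow, and transient conjugate heat transfer with phase change over a freezing
session of tens of minutes. Its purpose is quantitative treatment-planning
style questions: how iceball and lethal-zone volumes depend on the
probe-to-vessel distance $L_d$ and the inlet velocity $V$, how much heat the
artery injects, and how long a session can run before the artery wall itself
reaches freezing.

## Model

### Tissue: Pennes equation with an effective heat capacity

Tissue temperature $T_t$ obeys the Pennes bioheat equation with phase change
handled by the effective (apparent) heat capacity method:

$$\hat C(T)\,\frac{\partial T_t}{\partial t}
  = \nabla\!\cdot\!\big(\hat\kappa(T)\,\nabla T_t\big)
  + \hat\omega_{cb}\,C_b\,(T_{cb} - T_t) + \hat Q_m .$$

The transition band $[T_l, T_u] = [-8, -1]$ °C smears the phase change:
$\hat C$ equals the frozen capacity $C_f$ below the band and the unfrozen
capacity $C_t$ above it, and inside the band it is inflated by
$Q_f/(T_u - T_l)$ so that $\int \hat C\,dT$ across the band carries the latent
heat $Q_f$ plus the sensible part. $\hat\kappa$ blends linearly from
$\kappa_f$ to $\kappa_t$ across the same band. Capillary perfusion
$\omega_{cb} C_b (T_{cb} - T)$ and metabolic heat $Q_m$ act only in unfrozen
tissue ($T > T_u$): blood supply and metabolism cease once freezing begins.

Defaults (`material_properties()`): $C_t = C_b = 3.6$, $C_f = 1.8$ MJ/m³K,
$Q_f = 250$ MJ/m³, $\kappa_t = \kappa_b = 0.5$, $\kappa_f = 2$ W/mK,
$\omega_{cb} = 5\times10^{-4}$ 1/s, $T_{cb} = 37$ °C. $Q_m = 420$ is treated
as a volumetric heat generation *rate* (W/m³); at cryogenic gradients its
magnitude is negligible either way.

### Blood: steady flow plus advection–diffusion

The lumen carries an incompressible Newtonian steady laminar flow
($\mu = 2.5\times10^{-3}$ Pa·s, $\rho = 1050$ kg/m³ — the density is not part
of the printed parameter set because all capacities are volumetric, but the
momentum equation needs one; 1050 kg/m³ is the standard value for whole
blood). The flow is solved once and then frozen: blood in a large artery is
taken as unfreezable and its velocity as temperature-independent. Blood
temperature obeys
$$C_b\Big(\frac{\partial T_b}{\partial t} + V\cdot\nabla T_b\Big)
  = \nabla\!\cdot\!(\kappa_b \nabla T_b),$$
coupled to the tissue through the artery surface (zero wall thickness) as a
conjugate heat transfer problem. At $V = 0.2$ m/s the Reynolds number is
$\rho V D_0/\mu = 840$, safely laminar.

Boundary conditions: parabolic inlet profile $u(r) = 2V[1-(2r/D_0)^2]$ at
37 °C, zero reference pressure and zero-gradient temperature at both daughter
outlets, adiabatic outer tissue shell, fixed $T_p = -196$ °C on the probe
active tip, zero flux on the insulated shaft.

### Geometry

The tissue cylinder ($D_t = 120$ mm, $L_t = 100$ mm) has the root vessel
($D_0 = 10$ mm) along its axis; the bifurcation point sits at depth
$L_1 = 20$ mm and the daughters (cube law $D_1 = 2^{-1/3} D_0 = 7.94$ mm) span
the remaining $L_2 = 80$ mm of vertical extent. Probes are horizontal (along
y, normal to the bifurcation plane) with the active-tip midpoint on the
cylinder axis at depth $L_1 + L_d$.

The bifurcation angle needed a design decision. Read as the *full* angle
between daughters (each 30° from the axis), the tissue gap between the probe
surface and the daughter wall is $L_d/2 - 5.97$ mm: the probe *touches* the
artery at $L_d = 10$ mm and sits 1.5 mm away at $L_d = 15$ mm, which makes the
wall freeze within seconds at any resolution — incompatible with the
wall-freezing times this configuration is known to produce (~10 s at
$L_d = 10$, over a minute at $L_d = 15$, indefinitely protected at
$L_d \ge 20$ for moderate flow). Read as each daughter's angle *from the root
axis* (60°), the gap becomes $0.866\,L_d - 5.97$ mm (2.7 / 7.0 / 11.4 / 20 /
28.7 mm at $L_d = 10\ldots40$), which reproduces those times and the
"iceball stops at the artery" behavior at $L_d = 20$. `cryovessel` therefore
defaults to the axis-referenced angle (`phi_ref = "axis"`); the other reading
remains available. To fit the 60° departure inside the cylinder, each daughter
bends back to the vertical on a circular arc (`bend_radius = 40` mm by
default) and then runs straight to the bottom outlet — the "curved tube" shape
of hepatic-type bifurcations. The arc radius is not printed anywhere; 40 mm
keeps the outlets ~20 mm off-axis, comfortably inside the tissue.

A probe may approach the lumen to within grazing contact in the tightest
configurations; placement is rejected only when the analytic penetration
exceeds `max_overlap` (1.5 mm default), with a warning for sub-tolerance
contact. On the grid, probe labels take priority over lumen.

For the three-probe layout (`three_probe_layout()`), the probes' axes are
parallel to the cylinder axis, with the active-tip midpoints on a horizontal
circle of radius 20 mm centered on the axis at depth $L_1 + L_d$. The
alternative reading — horizontal probes like the single-probe case — is
geometrically inadmissible here: with the daughters swinging out at 60°, the
two lower probes of a radius-20 mm horizontal-axis ring would pass through
the daughter lumen (2.3 mm penetration), whereas axis-parallel probes clear
it by more than 5 mm and still produce three separate, later-merging
iceballs.

### Discretization

Everything is solved on one uniform Cartesian voxel grid (spacing `h`), cells
labeled TISSUE / LUMEN / PROBE_TIP / PROBE_SHAFT / EXTERIOR by an analytic
membership test of the cell center with that priority order. This replaces
body-fitted tetrahedral meshing; the cost is stair-step walls, the benefit is
a fully self-contained, regression-testable solver. Known biases at desk
resolution, measured by the test suite: voxel label volumes converge at first
order in `h` (a thin 8 mm tube is ~20% heavy at `h = 2.5` mm, ~2% at 1 mm),
and the raw voxel surface overestimates a curved analytic area by the
L1-projection factor (4/π for a cylinder), which matters only for reporting
absolute interface areas, not for the solved fluxes.

**Flow.** `analytic_flow()` (desk default) orients a Poiseuille profile along
the local centerline tangent of the nearest branch (root carries the full
flux, each daughter half, so the far-daughter mean speed is
$2^{-1/3} V \approx 0.794 V$), zeroes wall faces, imposes the exact parabolic
inlet, and projects the face field to be discretely divergence-free (sparse
Cholesky Poisson solve with zero reference potential at the outlets). Mass
balance is then exact to machine precision and the field is mirror-symmetric.
`solve_steady_flow()` (convergence mode) is a staggered-grid (MAC)
pseudo-transient projection method: explicit first-order upwind advection,
implicit viscous diffusion, exact pressure projection every step, marched
until the per-step velocity change falls below `tol * V` (default 1e-6).
First-order upwinding is sufficient here because the acceptance checks for
the solved field (developed Poiseuille in a grid-aligned tube; symmetric 50/50
daughter split) are insensitive to the advection order; the temperature solver
offers a deferred-correction second-order upwind (`advection_order = 2`) for
sensitivity studies.

**Temperature.** One backward-Euler finite-volume step advances TISSUE and
LUMEN cells together in a single 7-point linear system: harmonic-mean face
conductivities (also across the artery surface), implicit first-order upwind
advection with the frozen face velocities, probe faces as Dirichlet values at
half-cell distance, perfusion treated implicitly. The effective-capacity
nonlinearity is resolved by a Newton-type enthalpy linearization: each
iteration solves with the apparent capacity $\hat C(T^{(k)})$ as the Jacobian
of the enthalpy residual $[H(T^{(k)}) - H(T^{\mathrm{old}})]/\Delta t$, where
$H$ is the closed-form integral of $\hat C$. At convergence the discrete
enthalpy balance holds exactly, so latent heat is conserved even when a cell
traverses the whole transition band within one step. Plain chord-capacity
Picard (with capacity under-relaxation) was tried first and limit-cycled at
the band edges; the Newton form converges in a handful of iterations
(tolerance 1e-3 °C max change, conductivity under-relaxed by 0.8 between
iterations, mild 0.5 damping after 12 iterations). The linear systems are
solved matrix-free by ILU(0)-preconditioned BiCGSTAB (relative tolerance
1e-6); on the 7-point stencil ILU(0) only modifies the diagonal and typically
converges in one or two iterations.

**Time stepping** follows the nonuniform schedule 0.005 s ($t<1$ s) /
0.01 s ($\le 5$ s) / 0.05 s ($\le 100$ s) / 0.1 s (beyond), multiplied by
`dt_scale`. Backward Euler is unconditionally stable, so the scale trades
temporal accuracy for speed only.

### Metrics

* **Iceball / lethal volume**: tissue with $T \le 0$ °C / $\le -40$ °C.
  Whole-cell counting plus a first-order sub-cell correction on every
  tissue–tissue face straddling the threshold (the marching-style crossing
  point between cell centers); the correction restores roughly O(h²)
  convergence on smooth fields, and plain counting remains available for
  sensitivity reporting.
* **Artery-surface heat flux**: sum of the discrete conjugate face fluxes
  (harmonic-mean conductivity), positive from blood into tissue.
* **Minimum wall temperature**: the artery wall has zero thickness, so the
  wall value is the *interface face temperature* from discrete flux
  continuity, $(\hat\kappa_t T_t + \kappa_b T_l)/(\hat\kappa_t + \kappa_b)$.
  Sampling the lumen cell centers instead (one candidate reading of "artery
  surface") sits $h/2$ inside flowing blood, where advection pins the
  temperature near 37 °C at any affordable resolution; the face value is the
  solver's own wall temperature and is the quantity whose 0 °C crossing
  defines the **treatment time** (linearly interpolated in time, `Inf` when
  the horizon is exceeded).
* **Point probes**: trilinear interpolation (exact on linear fields).

## Problem sizes and what they resolve

Two bundled fidelities:

* **desk** (`h = 2` mm, `dt_scale = 10`, analytic flow): a 20-minute session
  in about a minute of CPU. The spacing is chosen so the standard 4 mm probe
  rasterizes at exactly its own width (cell faces aligned with the probe
  surface); at 2.5 or 1.25 mm the probe footprint is one cell too fat, which
  alone shifts wall-freezing times by ~35%. Desk runs resolve bulk volumes to
  roughly 10–30% and all parameter-study *orderings*.
* **convergence** (`h = 1` mm, `dt_scale = 1`, solved flow): the fidelity for
  quantitative claims; a full 20-minute case at this setting is an hours-long
  batch run, but short wall-injury horizons (a minute or two of simulated
  time) complete in ~10 minutes.

Resolution is the binding constraint for the *vessel-protection* physics. The
blood-side thermal boundary layer in the entrance/bifurcation region is
thinner than 1 mm; the discrete wall-to-blood conductance `2 kappa_b / h`
under-supplies heat to the wall for `h > ~1` mm, so at desk resolution the
artery wall eventually freezes in configurations where it should plateau a
few degrees above zero, and from that moment the artery loses much of its
iceball-suppressing effect. Consequences visible in the test suite at its
stated problem sizes: probe-distance and inlet-velocity *orderings* hold
strictly, near-field volume and timing values land within the 20% reference
bands, but the mid-distance iceball (probe 30 mm from the bifurcation), the
lethal volume, the near-contact wall-freezing time, the far/slow-flow
"never freezes" sentinel, and the wall-plateau value itself exceed their
bands at desk resolution; all of them move toward the reference under
refinement (measured at h = 2.5 → 2 → 1.25 → 1 mm during development). The
time-step scale is benign by comparison: doubling it from 10 to 20 changes
20-minute volumes by well under 0.1%, so the 20-minute suite runs use scale
20 with metrics at the end time.

## Verification strategy

The `verification` layer contains closed-form oracles with no dependence on
the solver: the two-phase Neumann–Stefan similarity solution (front
coefficient by bracketing bisection of the transcendental residual, checked in
tests against an independent brute-force residual scan), the single-phase
semi-infinite erf solution, and deterministic fixtures (`single_cell`,
`slab_1d`, `straight_tube`, `mini_bifurcation`). The solver is held to:

* erf-solution agreement on a frozen slab (pure conduction) to < 2%;
* Stefan front position within 5% after two grid/time refinement levels with
  observed order ≥ 1 — the oracle has a sharp front at
  $T_m = (T_u + T_l)/2 = -4.5$ °C while the solver smears the transition over
  7 °C, so the comparison tolerance budgets that difference;
* exact-at-convergence enthalpy bookkeeping (global energy balance < 0.5%);
* the discrete maximum principle for the implicit upwind step;
* mirror symmetry of geometry, flow and temperature under reflection across
  the bifurcation plane.

The synthetic fixtures emulate the *mechanisms* (phase change, conjugate
coupling, advection) at small sizes; they do not emulate patient anatomy,
pulsatility, vessel-wall mechanics, or freeze–thaw cycling, so passing tests
demonstrate correctness of the numerics under the stated model, not clinical
fidelity.

## Degenerate inputs and edge behavior

`V = 0` produces the zero flow field and pure conduction. `phi → 0`
degenerates the bifurcation to a straight tube. A zero freezing horizon
returns only initial metrics (zero volumes, 37 °C wall). Probes coarser than
the grid (`h > D_p`), grids that cannot hold a probe-tip cell, and probes
outside the tissue or inside the lumen are rejected with specific errors.
Simulation steps abort with diagnostics on NaN or on linear/Newton
non-convergence rather than silently continuing.

## Known limitations

* Stair-step walls: near-wall flow and wall fluxes carry an O(h) geometric
  bias relative to body-fitted meshes; the daughter-split and Poiseuille
  checks quantify the flow side, the volume-convergence tests the geometric
  side.
* The wall boundary layer is the binding resolution constraint for
  vessel-injury timing (see above).
* The probe footprint rasterizes ~h/2 too wide, inflating early lethal-zone
  volumes at coarse h.
* Single-session freezing only: no thaw/refreeze cycles, no cryoprobe
  internal refrigerant model, no nanoparticle or external-field wall
  protection, no pulsatile or non-Newtonian flow.
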