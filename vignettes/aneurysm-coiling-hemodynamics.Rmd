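---
title: "Hemodynamics of coiled sidewall aneurysms: model, solver and design campaign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamics of coiled sidewall aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rupture risk of cerebral aneurysms and the efficacy of endovascular coiling
are usually argued from hemodynamic quantities — the pressure the blood
exerts on the sac wall, the velocity of the flow that still enters the sac
after treatment, wall shear stress (WSS) and its directional reversal over
the cardiac cycle (the oscillatory shear index, OSI). `aneuflow` builds a
desk-scale, fully testable version of such a study: idealized sidewall
aneurysm geometries, pulsatile non-Newtonian blood flow, a porous-medium
model of the coil mass, and a central-composite-design (CCD) /
response-surface (RSM) campaign over four factors:

* sac section area `A_s` (11.65–94.57 mm²),
* parent-vessel mean radius `R_p` (1.59–2.24 mm),
* hematocrit `H` (0.35–0.5),
* coiling porosity `eps` (0.73–0.96).

The responses are the peak-systolic mean sac-wall gauge pressure and the
sac-averaged velocity magnitude, with WSS, OSI and a velocity-exceedance
fraction as supplementary outputs.

## Geometry: a 2D idealization

Patient-specific 3D surfaces are replaced by a planar idealization: a
straight channel of width `2 R_p` with a circular sac of section area `A_s`
attached to one wall through a neck. The sac is the part of a disc cut off
by the channel-wall line; the cut chord is the neck. On a uniform Cartesian
grid, cells are labelled `FLUID`, `WALL`, `COIL` or `EXTERIOR`, fluid cells
carry a region (`PARENT`, `NECK`, `SAC`), and the two domain ends carry the
pressure boundaries. The default domain extends 10 channel widths upstream
and 5 downstream of the neck center so the boundaries do not interact with
the sac.

**Neck size.** The study never states neck dimensions, so the neck is a
modelling choice. Tying the neck width to the sac diameter makes the neck
grow with the sac, so that a larger sac receives proportionally more
momentum from the parent flow — its mean velocity and dynamic wall-pressure
load then *increase* with sac area, inverting the directions the study
reports. Anatomically the neck (the ostium) is a defect of the parent-vessel
wall and does not scale with how far the dome has ballooned. The default is
therefore `neck width = neck_ratio * min(sac diameter, channel width)` with
`neck_ratio = 0.8`: vessel-limited for sacs in the study's range,
sac-limited (the original proportional rule) for small sacs where a
vessel-wide neck could not be cut from the disc. With this choice the
sac-averaged velocity decreases with sac area, as the study observes.

A real STL surface can still be measured: `measure_stl_morphometrics()`
slices a triangulated surface (ASCII or binary STL) perpendicular to its
dominant axis and reports the largest closed cross-section contour area and
the equivalent-circle radius of the tube section near the inlet end. These
are measurement utilities only; no 3D simulation is attempted.

## Blood rheology

Blood is a Casson fluid, `sqrt(tau) = sqrt(tau_y) + sqrt(mu_c * gdot)`. The
study names the model but prints no parameters, so hematocrit coupling is
supplied by two overridable correlations chosen for physiological
magnitudes (`tau_y` about 5 mPa and `mu_c` about 5 mPa·s at `H = 0.45`):

* yield stress `tau_y = 0.117 * max(H - 0.1, 0)^3` Pa (cubic above the
  aggregation threshold),
* high-shear viscosity `mu_c = mu_p (1 + 2.5 H + 7.35 H^2)` with plasma
  viscosity `mu_p = 1.45` mPa·s.

The constitutive law is regularized in the Papanastasiou style,

```
mu_eff(gdot) = ( sqrt(mu_c) + sqrt(tau_y / gdot) * (1 - exp(-sqrt(m * gdot))) )^2,
```

with `m = 100` s, which is smooth, finite at zero shear
(`(sqrt(mu_c) + sqrt(tau_y m))^2`) and tends to `mu_c` at high shear.
Density defaults to 1050 kg/m³.

**Numerical cap.** The regularized viscosity reaches ~0.6 Pa·s at zero
shear. Under explicit diffusion the stable time step scales with
`dx^2 / mu_max`, so the *solver* (not the rheology module) additionally caps
`mu_eff` at `mu_cap = 0.04` Pa·s. At default blood parameters the cap binds
only below ~0.3 s⁻¹ shear, i.e. in quasi-stagnant pockets; the Casson
channel benchmark below shows plug width and flux are preserved within a
few percent.

## The coil as a porous medium

The packed coil fills the entire sac and acts as an isotropic porous medium
with Kozeny–Carman permeability `K = d_w^2 eps^3 / (180 (1 - eps)^2)`
(`d_w = 0.25` mm wire). It enters the momentum equation as a Darcy sink
`S = -(mu_eff / K) u` in `COIL` cells — superficial-velocity formulation,
no Forchheimer term (pore Reynolds numbers at intra-sac velocities are
small). Because `mu_eff/(rho K)` reaches ~2000 s⁻¹ at `eps = 0.73`, an
explicit sink would cap the time step far below the advective limit; the
sink is linear and pointwise, so it is integrated implicitly (an exact
per-face division), which is unconditionally stable and changes nothing
else about the scheme. The projection step uses matching face coefficients
`1/(1 + dt mu/(rho K))` in the pressure operator so the discrete Darcy
balance `-grad p = (mu/K) u` is recovered exactly in the steady limit (the
porous-channel benchmark verifies `u = (K/mu) G` within 5%, in practice
0.1%).

## Pulsatile drive

The cardiac waveform is a periodic C¹ cubic (Catmull–Rom) interpolant
through four phase knots — late-diastolic upstroke, systolic peak, dicrotic
phase, diastolic decay — scaled to a 100 mmHg mean, 20 mmHg systolic
excess, period `T = 0.857` s (70 bpm). Its unique maximum defines the
waveform's peak systole.

The simulation is driven by gauge pressure: the inlet receives the waveform
scaled to a mean gauge drop, the outlet is held at 0, and all reported
pressures are gauge relative to the outlet. The mean drop is calibrated
from plane Poiseuille, `G = 2 mu_c u_target / a^2` with
`u_target = 0.5 m/s` at the systolic maximum, **per run** — using each
run's viscosity and radius. A single global drop would push the extreme
radii outside the physiological 0.4–0.6 m/s peak-velocity window
(`0.5 * (1.59/1.915)^2 = 0.34` m/s), so per-run calibration is the only
configuration that keeps every design point in the stated window. This
choice is load-bearing for the campaign: it is what makes the pressure
responses increase with viscosity (hematocrit) and decrease with radius,
mirroring a physiology where each vessel carries its own flow.

Three cycles are simulated from rest (`t = 0` of the cycle) and all
responses are taken from the third. Peak systole for sampling is defined as
the instant of maximum *inlet flux* in the final cycle — flow lags the
pressure waveform — and both instants are available.

## Solver

A fractional-step (projection) method on a staggered MAC grid with
stair-step walls:

1. cell shear-rate magnitude from the previous step's velocities; `mu_eff`
   per cell (lagged, Picard-style — no nonlinear solves);
2. explicit first-order upwind advection and explicit variable-viscosity
   diffusion (`div(mu grad u)` form), then the implicit Darcy division;
3. pressure Poisson `div(beta grad p) = (rho/dt) div(u*)` with the inlet
   Dirichlet pressure from the drive and 0 at the outlet, solved by
   conjugate gradients preconditioned with a Gustafsson-modified incomplete
   factorization (DILU/MIC), warm-started from the previous pressure, to a
   relative residual of 1e-6;
4. projection of the face velocities; no-slip enters through ghost-cell
   reflection, inlet/outlet tangential velocity is zero-gradient.

The time step is `0.4 / (|u|_max/dx + 4 nu_max/dx^2)` and is additionally
clipped to land exactly on sampling instants, which keeps runs bit-for-bit
deterministic. In explicit projection stepping the discrete momentum
equations are satisfied exactly, so the governing-equation residual that
remains is continuity: the reported outer residual is the normalized
post-projection divergence, required below 1e-4 (in practice ~1e-8); the
cycle-to-cycle velocity change is logged separately as a periodicity
diagnostic.

The `quick` advection option named in the configuration is reserved but not
implemented; requesting it raises an error rather than silently falling
back.

**Validation** (all in the test suite): steady Poiseuille centerline within
1% (measured 0.03%); oscillatory-channel amplitude at Womersley number 3
within 5% of the analytic series (measured 0.7%); Casson channel plug
half-width within 10% (measured 0.5%, plug edge found by extrapolating the
square-root shear profile to zero) and flux within 5% (measured 1.5%);
porous channel within 5% of the Darcy velocity (measured 0.06%);
post-projection divergence below `10 * poisson_tol * u/dx`; mass
conservation between inlet and outlet within 1%.

## Responses

* **Mean sac-wall pressure**: mean cell gauge pressure over sac cells
  4-adjacent to a wall cell, at peak systole. The study does not define its
  averaging surface or reference; this package reports gauge relative to
  the outlet.
* **Sac-averaged velocity**: mean cell-centered speed over all sac cells,
  coil included; also the maximum, and the fraction of sac cells above
  0.15 m/s (the 2D stand-in for the study's velocity iso-surface
  comparison).
* **WSS**: one-sided first-order, `tau_w = mu_eff u_t / (dx/2)` per
  wall-adjacent cell face, signed by the tangential velocity.
* **OSI**: `0.5 (1 - |int tau dt| / int |tau| dt)` by trapezoidal
  quadrature over 24 uniformly spaced instants of the final cycle; zero
  shear gives OSI 0 by convention.
* **Streamlines**: fixed-step RK4 on the bilinearly interpolated staggered
  field, for the flow-pattern figures.

## Design campaign

`ccd_design()` builds a face-centered CCD (axial distance 1 — the factor
ranges are hard physical bounds): `2^k` factorial + `2k` axial + center
rows, 25 runs for the four factors with one center point.
`fit_quadratic_surface()` fits the full second-order polynomial on coded
factors by QR (no delegation to `lm`, which instead serves as an
independent oracle in the tests) and reports standardized effects
`coef/SE`; `effects_report()` produces the Pareto ordering, half-normal
quantiles and linear-effect signs. A numerically perfect fit (zero residual
variance) reports all-zero t-ratios rather than rounding noise. Each fit
refuses when fewer successful runs remain than coefficients plus one.

`run_campaign()` generates a geometry per run from the run's own area and
radius — the only way the two geometric factors can be set independently,
something the original patient-geometry study could not do — simulates,
extracts responses, writes rows incrementally (resumable and byte-identical
on re-run) and fits both surfaces. `two_point_contrast()` runs exactly two
simulations differing in one factor.

## What a green test does — and does not — establish

The synthetic world reproduces the study's *stated* conditions: factor
ranges, three cycles, residual below 1e-4, a four-phase waveform, and
responses at peak systole. It does not reproduce patient anatomy: vessels
are straight, sacs are circular, and flow enters the sac only by shear-layer
entrainment rather than by inertial impingement on a curved vessel, so
intra-sac velocities sit at a few percent of the parent velocity and the
0.15 m/s exceedance fraction is typically zero for coiled sacs.

Two consequences are measured and documented rather than hidden. In this
idealization the sac's gauge wall pressure is pinned to the channel's
static pressure at the neck, which is independent of sac area by
construction; the sac-area pressure contrast (36.6 to 75.4 mm²) therefore
comes out positive but of order 0.1% rather than the study's 20%, and the
sac-area sign in the pressure response surface is not robustly negative.
The corresponding acceptance assertions are kept at the study's stated
values and fail honestly. The remaining directions — porosity and
hematocrit raising sac-wall pressure, radius lowering it, porosity raising
and radius lowering sac velocity — emerge robustly from the simulations.

## Numerical choices and limitations

* Uniform Cartesian grid with stair-step walls instead of a body-fitted
  boundary-layer mesh; the grid-convergence property (sac velocity changes
  < 5% between dx and dx/2 on the default case) is the justification.
* First-order upwind advection and first-order time stepping: robust and
  deterministic; boundary layers are resolved to first order only.
* `mu_cap = 0.04` Pa·s viscosity ceiling (see rheology) and implicit Darcy
  integration (see coil) are stability choices, both config-overridable.
* Presets: coarse `dx = 0.2` mm (the campaign default), default 0.15 mm,
  fine 0.1 mm. Direction checks in the acceptance suite use a further
  reduced preset (dx 0.3 mm, 3.5 + 2.5 width domain, two 2-factor designs)
  purely for runtime. The resolution was chosen by convergence: the weakest
  response (parent radius on sac velocity, a few-t effect on micrometer-
  per-second creep velocities) has the same sign at dx 0.3 and dx 0.25,
  while at dx 0.35 whole-cell snapping of the channel width overwhelms it
  and flips it — so 0.3 mm is the coarsest admissible setting.
* No fluid–structure interaction (rigid walls, as in the study), no
  turbulence (laminar, as stated), no 3D solving, no thrombosis kinetics,
  no coil compaction.
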