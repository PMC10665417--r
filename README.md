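# aneuflow

Desk-scale computational hemodynamics of coiled sidewall cerebral
aneurysms, for biofluid-mechanics researchers who want a fully
reproducible, testable stand-in for patient-specific CFD studies of
endovascular coiling.

The package simulates pulsatile, incompressible, laminar flow of
hematocrit-dependent Casson blood through idealized 2D sidewall-aneurysm
geometries, models the packed coil as an isotropic porous medium, and runs
a response-surface campaign over the four study factors — coiling porosity
`eps`, hematocrit `H`, sac section area `A_s` and parent-vessel mean radius
`R_p` — to quantify their effects on sac-wall pressure and intrasac
velocity.

At its core:

* **Rheology** — regularized Casson law
  `mu_eff = (sqrt(mu_c) + sqrt(tau_y/gdot) (1 - e^{-sqrt(m gdot)}))^2` with
  `tau_y = 0.117 max(H - 0.1, 0)^3` Pa and
  `mu_c = mu_p (1 + 2.5 H + 7.35 H^2)`.
* **Coil model** — Kozeny–Carman permeability
  `K = d_w^2 eps^3 / (180 (1-eps)^2)` feeding a Darcy momentum sink
  `S = -(mu_eff/K) u` in the sac.
* **Solver** — fractional-step projection on a staggered MAC grid,
  explicit upwind advection, explicit variable-viscosity diffusion,
  implicit Darcy sink, MIC-preconditioned conjugate-gradient pressure
  Poisson; pulsatile pressure drive with four cardiac phases; three cycles,
  responses at peak systole of the third; continuity residual < 1e-4.
* **Metrics** — mean sac-wall gauge pressure, sac-averaged velocity, WSS,
  OSI `= 0.5 (1 - |∫tau dt| / ∫|tau| dt)`, velocity-exceedance fraction,
  streamlines.
* **DOE/RSM** — face-centered central composite design (`2^k + 2k + n_c`
  runs; 25 for the four factors), full quadratic fit with standardized
  effects, Pareto / half-normal reports.

## Worked example

One campaign case at a reduced grid preset (blood at `H = 0.45`, coil at
`eps = 0.845`, sac of 36.6 mm² on a 1.9 mm parent vessel):

```r
library(aneuflow)

props <- derive_casson_parameters(hct = 0.45)
print(props)
#> blood_properties (Casson):
#>   rho = 1050 kg/m^3, hct = 0.450
#>   mu_p = 0.00145 Pa.s, mu_c = 0.005239 Pa.s, tau_y = 0.005016 Pa
#>   regularization m = 100 s

coil <- coil_model(porosity = 0.845, wire_diameter = 0.25e-3)
print(coil)
#> coil_model: porosity 0.845, wire 0.25 mm, K = 8.72e-09 m^2

cfg <- campaign_config(dx = 0.35, lu_widths = 3.5, ld_widths = 2.5)
res <- run_single_case(cfg, list(sac_area = 36.6, parent_radius = 1.9))
print(res$summary)
#> hemodynamic_summary (peak systole of final cycle):
#>   mean sac-wall pressure : 13.9 Pa gauge (0.104 mmHg)
#>   mean sac velocity      : 0.0002179 m/s (max 0.006649)
#>   mean sac-wall WSS      : 0.00548 Pa
#>   max OSI                : 0
#>   fraction |u| > 0.15   : 0
#>   peak systole at t = 2.0246 s
```

Reading the numbers: the sac-wall pressure is gauge relative to the domain
outlet — the ~14 Pa is the viscous pressure drop remaining between the
aneurysm neck and the outlet at peak systole. The densely coiled sac is
nearly occluded: mean intrasac speed is 0.2 mm/s, more than three orders below the
~0.5 m/s parent-vessel peak, no sac cell exceeds the 0.15 m/s threshold,
and the wall shear never reverses (OSI 0). Peak systole is detected at
`t = 2.02` s, shortly after the third cycle's systolic pressure peak, since
flow lags pressure.

The full 25-run campaign and the response surfaces:

```r
cfg <- campaign_config(outdir = "campaign_out")   # coarse preset, dx = 0.2 mm
res <- run_campaign(cfg)
print(res$fit_pressure)    # standardized effects on sac-wall pressure
print(effects_report(res$fit_pressure)$pareto)
```

A thin CLI wraps the same functions (`inst/exec/aneuflow`):

```sh
Rscript inst/exec/aneuflow design --out design.csv
Rscript inst/exec/aneuflow run --outdir campaign_out --resume
Rscript inst/exec/aneuflow contrast --factor sac_area --a 36.6 --b 75.4
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's headline computation from
scratch — the two coarse-preset simulations contrasting sac areas 36.6 and
75.4 mm² (all other factors at their range centers) and the relative change
of peak-systolic mean sac-wall gauge pressure — and writes its JSON output
to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The run takes on the order of 10 minutes on one CPU; progress and the
computed contrast are reported on stderr.
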