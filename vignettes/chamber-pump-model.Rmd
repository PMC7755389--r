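---
title: "The gasket-less chamber pump: model, numerics and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gasket-less chamber pump: model, numerics and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(syconpump)
```

This vignette is the package's account of the science it implements: the
flow model of a calcareous-sponge flagellated chamber, the analytic
pump/system framework, the tracer and experimental-statistics layers, the
numerical choices behind each, and what the desk-scale profiles can and
cannot resolve.

## The physical problem

Choanocytes pump water perpendicular to the chamber wall and through their
own microvillar collar filters. In leuconoid sponges a physical gasket
(Sollas' membrane) seals the collar tips so the pump can work against the
high resistance of a narrow canal system. Calcareous sponges (ascon/sycon
grades) lack the gasket; the question the model answers is how their open
chambers still force inhaled water through the collars instead of letting it
bypass them, and what trade-offs (pumping rate versus retention) that open
architecture implies.

## Geometry: the unit cell

The chamber is a cylinder (~85 um diameter) perforated by many ostia, each
surrounded by a ring of choanocytes. Because the ostia recur periodically,
the model domain is a single rectangular unit cell:

* floor: the chamber wall, 3 um thick, pierced by one central tubular ostium
  (diameter 7 um) — a uniform-pressure inlet is applied over the ostium
  mouth;
* 24 collars (diameter 2.5 um, length 4.8 um) with their flagella on a
  5 x 5 square lattice at the 5 um flagellar spacing, the ostium occupying
  the central site (24 = 5^2 - 1);
* top: a uniform-pressure outlet 20 um above the wall, where the cell opens
  into the chamber core (pressure variation in the core is negligible
  compared to the near-wall dynamics);
* x periodic (the chamber's long axis), z mirror-symmetric (azimuthal
  sides).

The true wedge of a cylindrical chamber is flattened into this slab: the
wedge angle per ostium is small, so wall curvature is a second-order effect,
and a Cartesian cell admits a structured-grid solver. Microvillus spacing
(0.05 um) is the clear gap between 0.1 um microvilli (centre-to-centre
0.15 um).

## Collar permeability

The collar wall is a row of parallel, equally spaced cylinders (microvilli).
`collar_resistance()` homogenises it into a Darcy-type wall resistance
`dp = alpha * U * t` with `t` the wall thickness. The drag per microvillus
uses the near-contact (lubrication) solution for creeping flow through the
gaps of a cylinder row,

    F/(mu U) = (9 pi sqrt(2) / 16) * L^2 sqrt(a) / b0^(5/2) * (1 + 0.27 (g/d)^0.58)

(`L` pitch, `a` radius, `b0` half-gap, `g/d` gap/diameter ratio). The
density-correction factor was calibrated once against resolved
two-dimensional Stokes computations of the exact configuration (a sparse
saddle-point solve, kept in the test suite as an independent oracle) at
gap/diameter ratios 0.25-5, and is accurate to within ~5% there; the classic
small-parameter series for dilute rows under-predicts the drag several-fold
at the collar's dense ratio (g/d = 0.5). The test suite verifies the closed
form against the oracle at ratios off the calibration points, within 10%.

The resulting wall resistance is ~1 Pa s um^-1: far larger than the
whole-unit pump pressure (~0.03-0.06 Pa) divided by realistic through-wall
velocities. Filtration through such a wall is possible only because the
confined flagellum generates locally large pressure fluctuations inside the
collar — which is exactly the behaviour the simulations show (the confined
part drives nearly all of `Q_col`, the unconfined part nearly all of
`Q_ost`).

## Beat kinematics

Each flagellum is a thin sheet (flagellum plus vane, width 0.7 um in the
base case) beating in a plane, with transverse displacement

    d(s, t) = a (1 - exp(-(s/delta)^2)) sin(2 pi (s/lambda - f t) + phase)

a base-to-tip travelling wave (lambda = 5 um, f = 30 Hz). The base case
(a = 1, delta = 1 um) saturates to ~1 um amplitude along most of the length,
fitting inside the collar. The increased-amplitude modulation
(a = 5, delta = 22 um) keeps the amplitude small inside the collar and grows
to a maximum of 2 um at the tip; the flagellar length 15.7 um is chosen so
that the envelope peaks at exactly 2 um there. The displacement is written
in the axial coordinate and the sheet is compressed axially each phase so
the centreline stays inextensible (to ~0.1%, verified by test); marker
velocities are time derivatives at fixed arclength (4th-order finite
differencing of the implicitly defined marker map). Asynchronous-beat and
rotated-beat-plane variants take per-flagellum phase offsets and azimuths.

## Flow solver

At these scales the Reynolds number is ~1e-3 and the oscillatory
(Womersley) layer at 30 Hz is far thicker than the chamber, so each beat
phase is a steady Stokes problem ("quasi-static"). The solver (an Rcpp
kernel) uses:

* a staggered Cartesian (MAC) grid; artificial-compressibility pseudo-time
  iteration with implicit drag, run to a momentum-residual tolerance of
  3e-6 relative to the viscous force scale of the fastest sheet (global
  mass imbalance then stays below ~0.2% of `Q_ost`);
* volume penalization for solids, with signed-distance solidity and a
  permeability-type partial-cell drag `C mu/h^2 psi/(1 - psi)`; `C = 32`
  was calibrated once against the Hagen-Poiseuille closed form (tube-flux
  errors -2.1%, -0.8%, +1.1% at 8, 16, 24 cells per diameter) and then
  frozen — the same discrete tube reproduces the Poiseuille resistance of
  the reference ostium to ~1%;
* the collar walls as membrane resistances on the velocity faces cut by
  each collar cylinder (full wall resistance over one cell depth). A
  one-cell volumetric Brinkman shell was tried first and rejected: at
  affordable grid spacings it is several times thicker than the real
  0.1 um wall and robs the confined flagellum of its wall clearance,
  which both throttled the confined pump and dominated the power budget
  with spurious rubbing dissipation;
* the moving sheets as penalized direct forcing (coefficient
  `4000 mu/h^2`) of every face the sheet cuts: the full no-slip velocity on
  beat-normal and beat-tangential faces, zero on vertical faces (the small
  axial rescaling velocity is dropped so the prescribed motion is
  divergence-consistent). Penalized faces still feel pressure, so the sheet
  cannot act as a volume source; residual sheet slip scales as the inverse
  penalization and stays well below the beat speed. Hard (non-penalized)
  forcing was rejected because fully enclosed forced cells became permanent
  volume sources;
* uniform-pressure boundaries at the ostium mouth (optionally offset by a
  back-pressure) and the top of the cell; an in-phase, common-plane beat is
  mirror-symmetric about the beat plane at half a period, so only half the
  phases are solved and fluxes repeat.

Diagnostics per cycle: `Q_ost` (inlet flux), `Q_col` (net upward flux
through the collar-tip openings, which by continuity equals the net flux
drawn through the porous walls), the flagellar power (work of the
penalization forces), the total dissipation (viscous + membrane), the
stagnation height above the ostium, and the global mass imbalance. Power
and dissipation agree within ~10-20% at the bundled profiles, an energy
self-check.

## Profiles and problem sizes

Two bundled profiles set the grid and phase resolution:

* `test` (h = 1 um, 8 phases/period): 25 x 23 x 25 um on 14k cells; a full
  cycle takes seconds. The whole test-suite, including tracer ensembles and
  the pump characterisation, runs in well under half an hour on one CPU.
* `full` (h = 0.5 um, 8 phases/period): 115k cells, roughly 2-3 minutes per
  cycle; the acceptance script's five production cases take about a quarter
  hour.

Finer grids scale poorly on one CPU (h = 0.25 um is ~16x the cells and ~4x
the iterations of h = 0.5), which bounds what the package resolves (below).

## Pump characteristic and operating point

Creeping flow is linear, so a pumping unit is fully characterised by
`Q_max` (zero load) and `P_max` (stall): `P/P_max = 1 - Q/Q_max`. The basic
gasket-less pumping unit is one zero-length ostium (a perforation) with its
24 choanocytes; the tubular ostium is accounted for separately as the
system resistance `R_ost = 128 mu L_ost/(pi D_ost^4)`. `pump_samples()`
runs the unit at three back-pressures (linearity makes two sufficient; the
third is a check — fitted R^2 must exceed 0.999) and `operating_point()`
intersects the two lines: `Q/Q_max = 1/(1 + R_ost/C_pump)`. Phase sampling
matters here: with fewer than ~8 phases per period the cycle average
aliases badly (40% flux bias at 4 phases), which is why both profiles use
8. With 8 phases the round trip — characterise the unit, predict the
operating flow through the real 3 um ostium, compare with the direct
simulation — closes to within 14%.

## Tracers

Passive prey particles are seeded across the ostium mouth with density
proportional to the local inlet flux (or uniformly, in which case the
estimator re-weights by flux) and advected by RK4 through the
phase-resolved, periodically interpolated velocity field. A particle coming
within one grid cell of a collar surface at collar heights is captured
(the model assumes every encounter is a capture); crossing the top face is
bypass. Defaults: 2000 particles, dt = period/200, and three seeds when
error bars are wanted (binomial error ~1% near complete capture). No
diffusion: bacteria-scale prey at these flows have large Peclet numbers
over the ~ms transit.

## Experimental statistics and synthetic data

The experimental layer implements the assay arithmetic exactly: dye-front
jet speed times osculum area under plug flow (5-10 replicates per sponge,
10-20 mm fronts); per-ostium and per-choanocyte rates from whole-sponge
flux; bead-spike calibration (analysed volume = bead count / stock
concentration); retention `100 (C_in - C_ex)/C_in`, kept signed so medians
stay unbiased; and box summaries with type-7 quartiles and 1.5 x IQR
whiskers, reporting the mean with both s.e. and s.d. (conventions the
source material leaves unstated; picocyanobacteria are excluded by default
in the published assay and are simply not a class here).

The synthetic generator is the package's stand-in for the field data: per
sponge a latent retention per class (Normal, truncated at 100%; defaults
98/98/60% for Euk/HNA/LNA with 6% between-sponge s.d. across 10 sponges x 3
pairs), log-normal inhaled concentrations (Euk 10, HNA 400, LNA 600
cells/uL, sdlog 0.3), Poisson event counts over the bead-implied analysed
volume (50 uL nominal, 50 beads/uL stock), and a 1-event Poisson
contamination floor in exhaled samples so perfect retention never computes
exactly 100% spuriously. The noise model is a deliberately minimal
cytometry model: it emulates count statistics and between-sponge spread,
not gating error, instrument drift, or class misassignment — passing
recovery tests therefore validates the estimator arithmetic, not the
cytometry itself. All draws are deterministic functions of the seed.

## Known limitations

* **Sub-grid vane widths.** At h = 0.5 um the 0.3 and 0.7 um vanes differ
  by less than one face column, so the pumping-rate gain from widening the
  vane below the grid scale is under-predicted (the model gives ~+15%
  where the resolved reference is ~+53%). A coverage-weighted sub-grid
  forcing was tried and rejected: it made the entire sheet leaky without
  restoring the differential. Vane widths at or above the grid spacing
  (1.4 um) respond strongly.
* **Absolute rates.** The production profile under-predicts the absolute
  pumping rates of the resolved reference by roughly a factor of two
  (e.g. increased-amplitude `Q_ost` ~ 423 versus ~874 um^3/s); percent
  changes between cases are more faithful but inherit the vane limit.
* **Collar-wall permeability and the physical gasket.** With the
  cylinder-row wall resistance (~1 Pa s um^-1), adding the impermeable
  collar-tip baffle forces all flow through the walls and *reduces* the
  pumping rate, whereas the resolved reference reports a gain; reconciling
  that gain would need a wall one to two orders of magnitude more
  permeable than a 0.05 um-gap cylinder row. The package keeps the
  physically-derived, oracle-verified permeability and reports the
  consequence honestly.
* **Power comparisons across beat forms** follow the same confinement
  physics: with the increased-amplitude envelope the confined part of the
  flagellum nearly stops, so the computed power drops sharply relative to
  the base case rather than rising moderately.
* The chamber-scale grid-convergence study (`grid_convergence()`) is
  dominated by the vane-width quantisation between grids; pointwise
  convergence of the scheme is established on the Poiseuille benchmark
  instead.

## Design choices where the design was open

* Waveform family and flagellar length: the saturating-Gaussian travelling
  wave with L_f = 15.7 um is the simplest form consistent with all the
  stated kinematic facts (base amplitude ~1 um over most of the length;
  increased-amplitude tip maximum exactly 2 um).
* Wall-position calibration constants (partial-cell drag C = 32, the
  permeability density correction) were fixed against analytic or resolved
  oracles only, never against the target quantities the package reports.
* The collar flux surface is the collar-tip opening (equal, by continuity,
  to the lateral through-wall flux); the basic-unit inlet is the uniform
  pressure face at the perforation mouth. An `inlet_buffer` option exists
  to move the boundary upstream; it lowers `Q_max` by including the
  orifice entry resistance inside the unit and is off by default.
* Quartile convention type 7; "mean +/- 6%" style summaries report both
  s.e. and s.d.
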