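# syconpump

Hydrodynamics of the gasket-less sponge pump: creeping-flow simulation and
analysis of pumping and filtration in the flagellated chambers of calcareous
(syconoid/asconoid) sponges.

Leucon-type sponges seal each collar filter with a physical gasket
(Sollas' membrane) so that their choanocytes can pump against the high
resistance of a narrow canal system. Calcareous sponges such as *Sycon*
lack any such seal, yet pump and filter effectively. This package models how:
the beating vaned flagella drive a backflow that meets the inhalant jet just
above the ostium, forming a stagnation zone — a **hydrodynamic gasket** —
that routes the inhaled water through the microvillar collar filters without
any physical seal. It is aimed at biological fluid dynamicists and
functional morphologists studying suspension-feeder pumps.

## What the package computes

* **Unit-cell creeping-flow simulation** (`build_unit_cell()`,
  `solve_cycle()`): a periodic rectangular cell of the chamber wall holding
  one ostium (diameter 7 um, length 3 um) and its 24 choanocytes (collars
  2.5 x 4.8 um, flagellar spacing 5 um). Quasi-steady Stokes flow is solved
  at each beat phase on a staggered Cartesian grid (Rcpp kernel) with volume
  penalization for solids, a calibrated membrane resistance for the porous
  collar walls, and penalized direct forcing of the moving flagellar sheets
  (travelling wave `a (1 - exp(-(s/delta)^2)) sin(2 pi (s/lambda - f t))`,
  base case lambda = 5 um, a = delta = 1 um, f = 30 Hz, vane 0.7 um).
  Outputs: the pumping rate `Q_ost` through the ostium, the filtration rate
  `Q_col` through the collars, flagellar power, and the stagnation
  (hydrodynamic-gasket) height (`stagnation_height()`).
* **Pump/system characteristic framework** (`characterize_pump()`,
  `operating_point()`): the linear pump curve `P/P_max = 1 - Q/Q_max`
  intersected with the canal system line `P = R_ost Q`,
  `R_ost = 128 mu L_ost / (pi D_ost^4)`; a gasket-less unit with
  `R_ost/C_pump ~ 1` delivers half its maximum capacity.
* **Passive prey tracking** (`track_particles()`,
  `encounter_efficiency()`): RK4 advection of tracers through the
  phase-resolved flow, scoring collar encounters versus bypass.
* **Experimental pipeline** (`excurrent_flow()`, `inex_retention()`,
  `retention_summary()`): dye-front excurrent flux (jet speed x osculum
  area), bead-calibrated cytometry concentrations, and paired inhaled/exhaled
  (In-Ex) retention efficiency `100 (C_in - C_ex)/C_in` with box-plot
  summaries — plus a synthetic-data generator (`generate_inex()`,
  `generate_flux()`) that emulates the assay's statistical structure.

## Worked example

```r
library(syconpump)

geom <- reference_geometry()
kin  <- beat_kinematics()                  # base-case beat
flow <- solve_cycle(geom, kin, solver_config(profile = "test"))
flow
#> Time-averaged chamber flow
#>   Q_ost (pumping rate)    : 303 um^3/s
#>   Q_col (filtration rate) : 4325 um^3/s (x14.27 re-filtration)
#>   flagellar power         : 0.2173 pW
#>   phases solved: 4 (half period, mirror symmetry)

stagnation_height(flow)
#> # A tibble: 1 x 3
#>   height height_over_collar below_collar_tip
#>    <dbl>              <dbl> <lgl>
#> 1   4.75              0.989 TRUE
```

The chamber pumps ~300 um^3/s through the ostium at the coarse test profile
while the collars filter several times that volume (most of the chamber
water is re-filtered), and the vertical velocity above the ostium reverses
at 99% of the collar length — the hydrodynamic gasket sits right at the
collar tips, so inhaled water cannot bypass the filter. Tracer particles
seeded across the ostium mouth confirm this:

```r
flow <- solve_cycle(geom, kin, solver_config(profile = "test"),
                    keep_phases = TRUE)
encounter_efficiency(track_particles(flow, n = 800, seed = 1))
#> # A tibble: 1 x 6
#>   efficiency captured exited remaining  lost lost_fraction
#> 1          1      757      0        43     0             0
```

The pump/system framework explains why this architecture needs no seal:

```r
pump <- pump_characteristic(q_max = 1114, p_max = 0.058)
report_c_pump(pump$c_pump)        # 50 uPa s um^-3
operating_point(pump, system_curve(poiseuille_resistance(7, 3), pump))
#> # A tibble: 1 x 5
#>   r_hat q_hat_op p_hat_op  q_op   p_op
#> 1 0.978    0.506    0.494  563. 0.0287
```

With the reference ostium the resistance ratio is ~1, so the unit operates
at half its free-flow capacity — efficient enough for an open canal system,
and catastrophically throttled (`Q = Q_max/101`) if connected to a narrow
leucon-type canal system with a hundred-fold resistance, which is where a
physical gasket becomes indispensable.

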