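---
title: "Modelling calcium-modulated TRAIL apoptosis in heterogeneous cell populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium-modulated TRAIL apoptosis in heterogeneous cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(camapop)
library(dplyr)
```

## The scientific problem

Cancer cells can be sensitized to TRAIL (TNF-related apoptosis-inducing
ligand) by elevated cytosolic calcium, for instance after activation of the
mechanosensitive ion channel Piezo1 with the agonist Yoda1, with or without
resveratrol-enhanced lipid-raft recruitment of the channel. A recurring
experimental observation is *saturation*: raising cytosolic free calcium
beyond about 1 µM (the Yoda1 level) barely changes apoptosis, even though the
measured calcium keeps rising (to about 1.7 µM with Yoda1 plus resveratrol).

`camapop` implements the computational side of such a study end to end:

1. a general mass-action reaction-network container compiled to a fast
   derivative evaluator (`reaction_network()`, `build_rate_function()`);
2. stiff ODE simulation of a single cell over 24 h with threshold event
   calls — apoptosis when cleaved PARP (cPARP) exceeds 5×10⁵ molecules per
   cell, MOMP when half of the mitochondrial Smac pool has been released,
   and the hour of peak free cytosolic Smac (`simulate_cell()`,
   `fate_call()`);
3. Monte Carlo populations of 1000 cells with random-normal cytosolic Bcl-2
   (mean 1.98×10⁶, SD 9.91×10⁵) and XIAP (mean 1.01×10⁵, SD 9.91×10⁴)
   initial amounts, and viability as the percentage of cells that never
   cross the cPARP threshold (`simulate_population()`);
4. mapping of measured ratiometric calcium fluorescence to model calcium
   levels, normalized so the Yoda1 condition is exactly 1 µM
   (`normalize_calcium()`);
5. one-phase-decay regression of viability against calcium
   (`fit_one_phase_decay()`); and
6. the closed-form assay metrics used alongside the model: Yoda1
   sensitization, donor-quenching FRET efficiency, and median ratiometric
   calcium (`yoda1_sensitization()`, `fret_efficiency()`,
   `ratiometric_median()`).

## The packaged network is a synthetic reconstruction

The original study defines its reaction list, rate constants and initial
conditions in an appendix that is not redistributed here, so the model that
ships with this package (`ca_trail_model()`,
`inst/extdata/ca_trail_synthetic/`) is a *synthetic reconstruction*: an
extrinsic-apoptosis network in the EARM tradition whose rate constants were
calibrated once against the published summary outcomes (the printed event
hours and population viabilities) and then frozen. It is not a transcription
of any published parameter table, and individual rate constants should not be
quoted as measured quantities. Consequently the packaged timing and
viability numbers are best read as calibration checks — they demonstrate
that the mechanism reproduces the published behaviour, not that the
parameters are the published ones. The property-based test suite (mass-action
algebra, conservation laws, closed-form limits, seeded reproducibility,
round-trips) is independent of this calibration.

## Mechanism

The network contains 33 species and 23 irreversible mass-action reactions:

* **Receptor module.** TRAIL binds death receptor to form a DISC
  (`TRAIL + DR → DISC`), which catalytically activates caspase-8
  (`DISC + C8_pro → DISC + C8`). The tabulated TRAIL amount corresponds to
  the reference dose of 50 ng/mL; other doses scale the ligand count
  linearly. Receptor count limits DISC formation, which is why 200 ng/mL
  behaves almost identically to 50 ng/mL while 0.5 ng/mL (ligand-limited,
  ~30 DISC) activates caspase-8 on a visibly slower ramp — the origin of the
  ~4 h dose offset in every downstream event.
* **Calcium module.** Cytosolic calcium is a clamped catalytic species
  expressed in µM (it appears with equal stoichiometry on both sides of its
  reactions, so it is conserved exactly). Calcium activates the protease
  calpain, second order in calcium; free calpain is quenched
  stoichiometrically by its endogenous inhibitor calpastatin. This
  titration makes the calcium response ultrasensitive: below the
  calpastatin capacity (reached only above roughly 0.5 µM within the 24 h
  horizon) free calpain is negligible, while at 1 µM the inhibitor is
  exhausted within the first hour and the free-calpain plateau — whose
  height is the *same* at every saturating calcium level — is established
  almost immediately. That plateau, not the calcium level, drives the
  downstream kinetics; this is the model's explanation of why 1.0 µM and
  1.7 µM give indistinguishable trajectories.
* **MOMP module.** Caspase-8 truncates Bid; free calpain additionally
  *primes* tBid into a membrane-active form with ~2.4-fold higher
  Bax-activation efficiency (calpain processing of Bcl-2-family substrates).
  Active Bax is buffered 1:1 by cytosolic Bcl-2; only after the Bcl-2 pool
  is titrated out does free active Bax accumulate, dimerise, and assemble
  tetrameric pores (effectively fourth order in free active Bax). The
  two-stage oligomerisation separates the pre-exhaustion "leak" regime from
  post-exhaustion ignition by many orders of magnitude, which is what makes
  MOMP switch-like and makes the per-cell Bcl-2 draw an almost hard
  survival threshold.
* **Execution module.** Pores release Smac and cytochrome c; cytochrome c
  nucleates the apoptosome, which activates caspase-3; XIAP sequesters
  caspase-3 and is antagonised by released Smac (including displacement of
  XIAP from caspase-3:XIAP complexes) and degraded by free calpain at
  saturating calcium; caspase-3 cleaves PARP. XIAP also turns over
  constitutively (free XIAP decays; caspase-3:XIAP complexes decay releasing
  the caspase), with a half-life of about a day — slow enough to be
  irrelevant at saturating calcium, where calpain destroys XIAP within
  hours, but decisive at low calcium: there the XIAP brake erodes on the
  same timescale as the 24 h horizon, so whether a MOMP-positive cell
  crosses the cPARP threshold becomes a *graded* race between its XIAP draw
  and the time remaining after its Bcl-2-determined MOMP hour. That joint
  dependence on the two random draws is what spreads the low-calcium
  population between ~70% viability while the high-calcium conditions pin
  viability to the Bcl-2 ceiling alone (~47%).

## Event definitions and numerical choices

* **Reporting grid.** Trajectories are reported on integer hours 0–24, and
  every event is the first grid hour at/after its crossing, because all
  published outcomes are whole-hour timepoints. Ties for the Smac peak take
  the earliest hour.
* **MOMP criterion.** No numeric MOMP rule is published; the package calls
  MOMP when the Smac released from the mitochondrial pool (free cytosolic
  Smac plus its XIAP-bound and cleared descendants) reaches 50% of the
  initial pool. The fraction is exposed as `momp_fraction` and was fixed
  before, not after, the timing calibration; because release is switch-like
  the called hour is insensitive to it over a wide range.
* **Solver.** `deSolve::ode(method = "lsoda")` with `rtol = 1e-6`; the
  reporting contract projects values in `(-atol, 0)` to zero and errors
  below `-atol`, while the solver runs at a 10³-fold tighter absolute
  tolerance than the guard. The guard defaults to 1 molecule per cell:
  with pools spanning 10⁶ molecules, interpolated output values carry
  absolute wiggles of order 0.01–0.1 molecules whatever the tolerances, so
  a guard much below 1 molecule flags pure round-off; 1 molecule is still
  5×10⁻⁶ of the apoptosis threshold. The derivative evaluator never
  clamps: mass action is smooth, so a transient sub-zero excursion flips
  the sign of the consumption terms and self-corrects. Halving the
  tolerances changes no reported event hour (this is a test).
* **Calcium units.** Calcium stays in µM; the calcium-dependent rate
  constants are expressed per µM. No cytosolic-volume conversion is
  performed, avoiding a silent unit error.
* **"Calcium-free" condition.** Interpreted as calcium species = 0 µM
  (rather than a basal floor); with the calpastatin titration any level
  below ~0.1 µM is equivalent, so the choice is inconsequential.
* **1.7 µM reading.** The Yoda1+resveratrol concentration is read as a
  *total* of 1.7 µM, not an increment above 1 µM; to use the increment
  reading, pass your own panel to `panel_to_conditions()`.

## Population heterogeneity

Per-cell Bcl-2 and XIAP amounts are drawn from the stated normals. Two
details are deliberate:

* **Truncation.** Molecule counts cannot be negative. About 15% of the
  XIAP normal's mass lies at or below zero; the default rule redraws such
  samples (rejection sampling), which raises the realized XIAP mean by
  roughly 20%. The alternative rule (`truncation = "clamp"`) keeps zeros.
  The published description does not say which was used; the choice is
  recorded in the result metadata and the viability tolerances in the
  acceptance checks absorb the difference.
* **Substreams.** Each cell's draws come from a seed derived from the
  master seed and the cell index, so enlarging a population never
  reshuffles the cells already drawn, and per-cell simulations are
  order-independent.

## What the synthetic-data generator does and does not emulate

`generate_flow_events()` produces per-event Fluo-4 / Fura Red intensities
whose ratio distribution has median exactly `gain × calcium` under
multiplicative log-normal noise (defaults: σ = 0.3, 2000 events/condition,
200 s acquisition window) — the statistical structure the ratiometric
median and calcium normalization assume. It does not simulate instrument
artefacts (doublets, spillover, debris, autofluorescence), so passing
round-trip tests demonstrates the correctness of the summarisation and
normalization pipeline, not robustness to real cytometer pathologies. The
resveratrol-only calcium value is not published; the default panel carries
a clearly labelled synthetic placeholder of 0.2 µM.

## Worked example

A scaled-down version of the full study (the packaged default is 1000 cells
per condition; 40 cells keep the vignette fast — the methods and seeds are
identical):

```{r study, eval = FALSE}
study <- run_apoptosis_study(n_cells = 40, seed = 1)
study$condition_table
tidy(study$decay_fit)
autoplot(study$decay_fit)
```

Single-cell fates at the in vitro dose:

```{r single, eval = FALSE}
net <- ca_trail_model()
fate_call(simulate_cell(net, make_condition(50, 1)))   # Yoda1 calcium
fate_call(simulate_cell(net, make_condition(50, 0)))   # calcium-free
```

## One-phase decay fitting

`fit_one_phase_decay()` fits `y(x) = (y0 − plateau)·exp(−k·x) + plateau` by
unweighted Levenberg–Marquardt least squares, initialised at
`y0 = max(y)`, `plateau = min(y)`, `k = 1/median(x > 0)`, with bounds
`k ∈ [0, 100]` and `plateau ∈ [0, 100]`. Theoretical (simulated) and
experimental viability series can be fitted separately or jointly — both
are just data frames of `(calcium_um, viability_percent)`; the package
takes no position on which the original figure used.

## Problem sizes and runtime

One 24 h single-cell integration takes ~20–40 ms. The default tests run
populations of up to a few hundred cells; the acceptance script runs the
full 1000-cell populations for the five calcium conditions (about 2–4
minutes in total). These sizes were chosen so the whole analysis reproduces
on a laptop-class single core in minutes.

## Known limitations

* The rate constants are calibrated, not measured; only the qualitative
  mechanism and the calibrated summary outcomes carry meaning.
* Bcl-2 and XIAP are drawn independently; correlated expression would
  change the joint survival boundary.
* Calcium is clamped; calcium dynamics (influx, buffering, extrusion) are
  out of scope.
* Only the extrinsic pathway is modelled; no transcription, synthesis or
  degradation beyond the reactions listed, so the model is meaningless far
  beyond the 24 h horizon.
* The one-phase-decay fit reports no confidence bands (none are used in
  the source figure); bootstrap machinery is deliberately absent.
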