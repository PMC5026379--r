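---
title: "hepapk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hepapk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hepapk simulates the disposition of a therapeutic oral dose of
acetaminophen (APAP) in a human, resolving three biological scales and
their coupling: a whole-body physiologically based pharmacokinetic (PBPK)
compartment model, a spatially resolved model of one representative liver
sinusoid with flowing blood, and a Michaelis-Menten reaction network for
Phase I/II metabolism inside each of twenty zonated hepatocytes.  This
vignette explains each model, its assumptions and parameters, the
numerical choices, and what the bundled tests do and do not demonstrate.

## The whole-body scale

The PBPK model tracks molar amounts (mmol) of one compound in ten
compartments: the gut lumen, gut, liver, venous blood, lung, arterial
blood, kidney, rest-of-body, and two sinks (kidney tubules, i.e. urine,
and a lumped "metabolized" pool).  Organs are well stirred and connected
by blood flows; tissue-to-plasma partition coefficients (`K*2p`), the
fraction unbound in plasma (`Fup`) and the blood-to-plasma ratio (`Rb2p`)
enter the venous return terms algebraically, so protein binding is
treated as instantaneous equilibrium.  Oral dosing is an initial
condition -- the full molar dose placed in the gut lumen -- not a forcing
term; repeated dosing is out of scope.

Three replicates of the same structure are run, one each for APAP and its
glucuronide (APAPG) and sulfate (APAPS) conjugates.  Metabolite
replicates start empty.  In the *standalone* whole-body model a lumped
hepatic clearance `pbpk_CLmetab` removes APAP; because its fitted value
is not published it defaults to zero and is user-supplied.  To produce
standalone metabolite curves, the metabolized flux is routed 60% to the
APAPG replicate and 33% to the APAPS replicate (the approximate human
urinary recovery shares), the remainder staying in the untracked pool.
In the coupled model this mechanism and `CLmetab` are disabled: the
sinusoid and hepatocyte scales carry hepatic elimination.

Gut absorption is first order (`kGutabs` = 1.5 /h) by default.  A
saturable, lagged variant is provided because clinical time courses
suggest transporter-mediated uptake: no absorption for ~9 minutes
(gastric emptying), then an approximately constant rate, modelled as
Michaelis-Menten uptake with `Km` small against the lumen content.

Body-weight handling: the reference flows and volumes are tabulated for a
70 kg male.  When `pbpk_bw` differs, flows scale allometrically as
`(bw/70)^0.75` and volumes as `bw/70`, which preserves the flow-balance
identity `QGut + QLiver + QKidney + QRest = QCardiac` (= 363.01 L/h at
reference).  Sensitivity and population runners fix the absolute dose in
mg from the *base* parameter set, so a body-weight perturbation changes
the physiology, not the administered amount -- this is what makes body
weight a dominant driver of exposure variability.

## The tissue scale: one sinusoid, deterministic parcels

The sinusoid is a 200 x 20 x 4 um channel lined on each side by 10
hepatocytes (20 x 20 x 20 um each), so hepatocyte axial spans tile the
lumen in 10 ranks of 2.  Blood is discretised into moving parcels: red
blood cells (400 um^3) and serum portions (100 um^3), created at the
periportal end by deterministic volume accumulators so that the long-run
RBC volume fraction equals the hematocrit (0.45) and the arterial:venous
provenance split is 1:3 by volume.  Every parcel is advected at 200 um/s
(plug flow), giving exactly a one-second transit, and is deleted at the
central-vein end with its content credited to an outflow accumulator.
Each newly created parcel is placed at the axial position corresponding
to its exact entry time within the step, which keeps the stream spatially
uniform and removes aliasing between the spawn cadence and the 20 um rank
width.

This deterministic parcel scheme stands in for a stochastic
multicellular (Cellular Potts) realisation of the same geometry.  The
justification is empirical: in such stochastic realisations, run-to-run
variation of the reported outputs is at the parts-per-billion level, so
the noise carries no
information and a deterministic abstraction that preserves the transfer
kinetics reproduces the same observables while being exactly repeatable
(bit-identical reruns, which the test suite asserts).

Solute exchange follows first-order mass-action transfer between
contacting entities, with the per-pair passive rate divided by the
source's neighbour count; an inwardly rectified saturable (active)
import of APAP from serum into hepatocytes; and first-order export of
the conjugates from hepatocytes into every contacting parcel (undivided,
as the rate table prints them).  Contact is geometric: a parcel touches
its axial predecessor/successor within a 10 um gap (about one RBC
length) and the two hepatocytes whose span contains it; hepatocytes
touch their same-side axial neighbours.  Two conventions deserve
emphasis:

* **Active import is parcel-level.**  A physical serum portion touches
  at most one vessel wall at a time, whereas an
  abstract parcel always spans both.  The saturable import is therefore
  applied once per parcel -- `Vmax_AT * C / (C + Km_AT * Fup)`, reaching
  half its maximum at `C = Km_AT * Fup` -- and split equally between the
  two flanking cells.  Applying it per contact pair would double the
  uptake and, at low concentrations, over-extract the upstream end of
  the sinusoid.
* **No-flux ghost neighbours at the ends.**  End-rank hepatocytes abut
  the portal-triad and central-vein structures; these occupy a neighbour
  slot but exchange nothing.  Keeping the neighbour count uniform
  prevents the rate-division from manufacturing artificial axial
  gradients at the boundaries.

At spawn, a stream blood concentration `C_blood` partitions between the
phases so that volume-weighted recombination returns `C_blood`: plasma
gets `C_blood / Rb2p` and RBCs the complement.  For the conjugates
(`Rb2p = 0.55 = 1 - hematocrit`, no RBC binding) the RBC load is exactly
zero; if a perturbed hematocrit would make it negative it is clipped and
the serum load renormalised, conserving moles.

CYP2E1 zonation: each hepatocyte's oxidation `Vmax` is scaled linearly
with axial rank from 80% (periportal) to 100% (pericentral); a
degenerate single-rank sinusoid uses 100%.

## The subcellular scale

Each hepatocyte runs an independent six-species network (mmol/L):
glucuronidation and sulfation of APAP (Michaelis-Menten; `Vmax` 1e-3 and
1.75e-4 mmol/L/s, `Km` 1 and 0.2 mmol/L), CYP2E1 oxidation to the
reactive quinone imine NAPQI (`Vmax` 2e-5 mmol/L/s scaled by zonation,
`Km` 1.29 mmol/L), second-order conjugation of NAPQI with glutathione
(GSH), and first-order GSH synthesis on the deficit
`kGsh * (GSHmax - GSH)` with `GSH0` = 9.9 and `GSHmax` = 10 mmol/L.
Cumulative NAPQI-GSH is the per-cell marker of toxic load.  Two printed
rate constants are dimensionally reconciled: the NAPQI + GSH rate
constant is second order and is used as 0.1 L/mmol/s, and `kGsh`
multiplies a concentration deficit and is used as 1e-4 /s.  Every
reaction except GSH synthesis conserves APAP equivalents, which gives the
suite a strict conservation oracle.  GSH never exceeds its ceiling, and
with no substrate its recovery follows the closed form
`GSHmax - (GSHmax - GSH0) exp(-kGsh t)` (used directly as an analytic
fast path when only the synthesis law is active).

## Coupling the scales

In the coupled model the PBPK liver compartment is bypassed: the
`CGut -> CLiver` and `CArt -> CLiver` flows are intercepted, their
flow-weighted mixture (`QLiver : QGut`, about 1:3.8) defines the inflow
blood concentration of the sinusoid, and whatever survives the transit
returns to the venous compartment.  The published 1:3 arterial:venous
ratio labels parcel provenance only.

**Scale factor.**  The single simulated sinusoid stands for the whole
liver through `S = VLiver * lumen_fraction / V_sinusoid` with
`lumen_fraction` = 7.4%, giving `S ~ 7.9e9` replicates.  All coupled
bookkeeping uses `S`: each step the gut/arterial compartments are debited
exactly `S` times the moles loaded into new parcels, the vein is credited
`S` times the drained outflow, and hepatocyte contents count `S`-fold in
the global ledger -- so conservation is exact by construction (the suite
verifies ~1e-14 relative over 8 h).  Note that `S` times the simulated
volumetric flow (16,000 um^3/s at the calibrated 200 um/s) is an
effective perfusion of ~455 L/h, larger than the PBPK hepatic blood flow
of 93.8 L/h: the tissue model's flow calibration and the whole-body
flows are independent, and blood *concentration* is deliberately the
scale-insensitive coupling variable.  The alternative, flow-matched
scale `(QLiver + QGut) / q_sinusoid ~ 1.6e9` is retained as a diagnostic
field; it under-represents hepatic capacity about five-fold and fails to
reproduce the human urinary recovery pattern, which is why the
volume-based factor is the package default.

**Quasi-steady-state (qss) mode** exploits the time-scale separation
(1 s transit versus hours of whole-body kinetics).  Each coupling step,
the steady state of the sinusoid for the instantaneous inflow is computed
by marching one co-moving RBC/serum parcel pair down the ten ranks (one
RK4 step per 0.1 s rank residence), with hepatocyte concentrations frozen
and parcel-parcel exchange taken at the expected neighbour statistics of
the streaming state.  Per-rank concentration drops, flow-weighted, give
the net molar flux into each rank's two cells; those fluxes and the
outflow return are then held frozen while the PBPK replicates (RK4,
substeps capped at 40% of the fastest compartment time constant) and the
20-cell reaction network (RK4, substeps capped by the NAPQI consumption
rate) advance.  The coupling step itself is chosen adaptively, at most
10 s and at most 40% of the fastest debit time constant (~3.5 s at
reference), keeping the frozen-flux splitting stable and accurate.

**Explicit mode** runs the literal cycle at the 16.7 ms flow step
(10 Monte-Carlo-step equivalents at 1/600 s each): advance PBPK, spawn
parcels, advect, transfer with conservative sub-stepping (halving until
no entity loses more than 20% of any compound per sub-step), advance the
cell networks, drain and settle the scaled ledger.  The suite checks
that the two modes agree on all model outputs to better than 1% over a
half-hour course (measured ~0.4%); explicit mode is the reference
dynamics, qss the fast default for 8 h and population work.

Serum concentrations are reported as venous plasma,
`(CVen / VVen) / Rb2p`, the quantity compared against clinical data;
ug/mL conversions use molar masses 151.16 (APAP), 327.29 (APAPG) and
231.23 (APAPS) g/mol.

## Model outputs, sensitivity and population analyses

`model_outputs()` assembles the 15-entry vector consumed downstream:
RMSE of each serum curve against a reference ADME table plus their sum
(linear interpolation onto the reference times; entries are NA sentinels
when no reference is supplied and are excluded from averages), Cmax,
Tmax (earliest time at the maximum) and trapezoidal AUC per compound,
the excreted metabolic ratio `(APAPG + APAPS)/(APAP + APAPG + APAPS)` in
the kidney tubules, and the `S`-scaled total NAPQI-GSH across all cells.

Local sensitivity uses the one-sided log-scale coefficient
`J_k = [(y_k(1.25 x) - y_k(x)) / (0.25 x)] * [x / y_k(x)]`, the +25%
finite-difference approximation of `d ln y / d ln x`; an optional
central-difference variant exists but is off by default.  The matrix
gains an `Average` row of column means over the defined entries.
Pairwise interaction coefficients subtract the two single-parameter
relative changes from the joint one; additively separable responses
score zero, and `y = x_i x_j` scores exactly 0.0625 at +25%.  Both are
verified against closed forms to 1e-12.  The default scan subset is
every compound-dependent parameter of the three scales plus body weight
and hematocrit (44 names); the exact published membership of the
38-parameter scan is not recoverable from the paper trail available to
the package, so the subset is user-overridable and ranked
`|Average J|` is reported without an importance threshold.

The virtual population multiplies every subset parameter of every
individual by an independent draw from Normal(1, cv = 0.25) truncated to
`[max(0.25, 1 - 3 cv), 1 + 3 cv]` -- bounds chosen to keep parameters
positive within +/-3 SD, since no published bounds exist.  Draws use the
inverse-CDF method so a seed fully determines the population, and
individuals are independent, so results are invariant to execution
order.  Flow balance is deliberately *not* re-imposed after perturbation.
Outliers are ranked by the signed area between an individual's serum
APAP curve and the population mean.  Fractions unbound can exceed 1
under multipliers; the simulator accepts this algebraically while the
strict file loader warns.

## Synthetic references

`generate_reference()` runs the model (standalone whole-body or coupled)
and samples the serum curves at requested times, optionally multiplying
each point by unit-mean lognormal noise of a chosen CV.  This stands in
for clinical calibration points, which are published only graphically:
it enables RMSE-based workflows, parameter-recovery exercises (the suite
recovers `kGutabs` within 5% from a noise-free reference after a +50%
misfit) and the sensitivity analyses.  What it does not emulate: real
assay error structure (correlated, heteroscedastic), sparse/irregular
sampling, inter-study variability, or model misspecification -- a fit
that recovers parameters from these references shows internal
consistency, not clinical validity.

## Problem sizes and tolerances

Standalone ODE integration uses a stiff-capable solver (lsoda) at
relative tolerance 1e-8 (whole-body; 1e-9 subcellular) and absolute
tolerances 1e-10 mmol / 1e-12 mmol/L.  The packaged checks run the full
8 h coupled course at reference settings, a 20-individual population at
cv = 0.25 for the urinary-recovery summaries (the published population
used 1000 individuals; 20 keeps a desk run in minutes and the population
*mean* fractions are stable well within the comparison bands), a
half-hour qss/explicit cross-check, and a 13-parameter scaled-down
sensitivity ranking over a 4 h course.  The acceptance script
(`scripts/acceptance.R`) recomputes the urinary composition from a fresh
20-individual population and the glutathione ceiling from a >20-half-life
standalone integration, writing bare numbers to JSON.

## Known limitations

One straight sinusoid represents all lobular flow paths: no network
topology, no velocity heterogeneity, no endothelium or space of Disse,
no bile route.  Overdose biology (GSH depletion to necrosis, reactive
oxygen species) is out of scope, as are covariate-structured populations
and correlated parameter sampling.  The parcel abstraction reproduces
mean transfer kinetics but not the cell-scale stochastic packing of real
(or Potts-model) blood; its contact statistics are a stated convention,
not an emergent property.
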