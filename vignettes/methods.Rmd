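---
title: "Methods: the GR trafficking model, its reductions, and regimen scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the GR trafficking model, its reductions, and regimen scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grpkpd)
```

## The seven-state trafficking cycle

The package implements a kinetic model of glucocorticoid receptor (GR)
trafficking between cytoplasm and nucleus. The receptor occupies seven
states: free cytoplasmic receptor `Rc`, loosely bound `RcG`, tightly
bound `RcGt`, tightly bound nuclear `RnGt`, the DNA-binding-competent
activated state `RnGN`, free nuclear receptor `Rn` and loosely bound
nuclear `RnG`. Two steps are instantaneous equilibria — the loose binding
reactions with dissociation constants `Kc` (cytoplasm) and `Kn`
(nucleus), the only ligand-dependent parameters — and six are
irreversible first-order transitions with shared rate constants
`k1` (RcG to RcGt, 10/min), `k2` (nuclear import, 0.2/min),
`k3` (activation, 0.2/min), `k4` (ligand release and recycling, 0.04/min),
`k5` (export of free nuclear receptor, 0.0017/min) and
`k6` (RnG to RnGt, 1/min). `gr_scheme()` exposes the edge list, which is
the single source of truth for both the steady-state solver and the ODE
right-hand side. Units are fixed package-wide: nM, minutes, min^-1;
total receptor `Rtot` is a scale factor defaulting to 1.

## Analytic steady state

With the loose steps at equilibrium, flux balance around the cycle gives
occupancies proportional, per unit of free nuclear receptor, to

- `Rc : k5 Kc / (k1 G)`, `RcG : k5/k1`, `RcGt : k5/k2`,
- `RnGt : (k5 + k6 G/Kn)/k3`, `RnGN : (k5 + k6 G/Kn)/k4`,
- `Rn : 1`, `RnG : G/Kn`,

normalised to `Rtot` (`gr_steady_state()`, `method = "closed"`). An
independent route (`method = "solve"`) solves the pooled flux-balance
linear system built from the edge list; the two agree to machine
precision and the test suite keeps them locked together. At infinite
concentration the receptor is confined to the nuclear tight cycle and

```{r}
rngn_max()   # (k6/k4) / (1 + k6/k3 + k6/k4) = 25/31
```

is the normaliser for all *relative activity* reporting
(`fRnGN / rngn_max`).

## Michaelis-Menten reductions and a known discrepancy

Two closed-form reductions are provided.

- **High-concentration** (`mm_high()`): export `k5` negligible, receptor
  fully nuclear. `fRnGN = VmaxH G / (KmH + G)` with
  `C = 1 + k6/k3 + k6/k4 = 31`, `VmaxH = (k6/k4)/C` and `KmH = Kn/C`.
  Inverting `KmH` against an experimental EC50 (`kn_from_kmt()`) is how
  the packaged `Kn` values were fixed (5 nM -> 155 nM for dexamethasone,
  50 nM -> 1550 nM for cortisol).
- **Very-low-concentration** (`mm_low()`): nuclear loose binding
  negligible; the receptor traverses the full cycle, rate-limited by the
  slow export. `D = k4 (1/k1 + 1/k2 + 1/k3 + 1/k4 + 1/k5)`,
  `VmaxL = 1/D`, `KmL = Kc k4 / (k1 D)`.

With the packaged rates these derivations give `VmaxH = 0.8065`
(identical to `rngn_max()`), `D = 24.93`, `VmaxL = 0.0401` and
dexamethasone `KmL = 0.000802` nM. The source reference prints
`VmaxH = 0.769`, `D = 31.5`, `VmaxL = 0.0317` and `KmL = 0.000787` nM
for the same quantities. We could not reconstruct any consistent closed
form reproducing the printed constants, while the derivation here is
verified against the full model (agreement to well under 1 % in each
reduction's validity regime, and exact inversion of the Kn values).
Both sets are therefore exposed side by side and diffed by
`gr_validation_report()` and `gr_consistency_report()`; nothing is
patched to match. The reference's printed affinity table also lists
different `KmL` values for prednisolone and methylprednisolone despite
identical `Kc`/`Kn` (`KmL` scales with `Kc`), which the ligand library
flags as a suspected erratum.

Validity regimes verified by the test suite: `mm_high` agrees with the
full model to within 5 % for `G >= KmT`; `mm_low` for `G <= 0.002 KmT`
(at `G = 0.01 KmT` the deviation already reaches ~15 %, so the often
quoted "1 % of EC50" is outside the 5 % band for these parameters).

## Time-dependent solution

`gr_simulate()` integrates the cycle under an arbitrary forcing profile
`G(t)`. Because the loose steps are instantaneous equilibria, the stiff
seven-state system is reduced to five pooled quantities
(`Rc+RcG`, `RcGt`, `RnGt`, `RnGN`, `Rn+RnG`) with time-varying bound
fractions `G/(Kc+G)` and `G/(Kn+G)`; the full trajectory is
reconstructed on output. Integration uses `deSolve::lsoda` with
`rtol = 1e-8`, `atol = 1e-12` (the rates span 10^-3 to 10^1 per minute)
and restarts at every profile discontinuity (dose events, chase
additions) rather than smoothing them. Mass conservation holds to
solver precision in every trajectory.

The cold-chase variant (`gr_chase()`) duplicates the tight states for a
labeled and an unlabeled species sharing the free pools; each loose
pool's tight-binding flux splits in proportion to the two free
concentrations. With zero unlabeled ligand it reduces (to ~1e-11) to the
one-species model. Under the packaged protocol (100 nM label for
100 min, then a 200-fold unlabeled excess) the labeled nuclear signal
plateaus before the chase and decays with a half-time of ~18 min,
inside the 15-30 min band expected from `ln 2 / k4 = 17.3` min.

## Forcing profiles and synthetic cortisol

Profiles are closures over `[0, t_end]` minutes (`gr_profile_constant()`,
`gr_profile_step()`, `gr_profile_table()`, CSV round-trip via
`gr_read_profile()`/`gr_write_profile()`). The packaged diurnal cortisol
curve (`gr_cortisol_profile()`) is a *synthetic stand-in* for measured
free-cortisol microdialysis data that are not available in tabulated
form: an asymmetric raised-cosine bump fixing the nadir (1.45 nM at
03:00) and peak time (08:00), whose two free parameters (peak height
29.57 nM, shape exponent 4.10) were calibrated once — by
`scripts/calibrate_cortisol.R`, then frozen — so the full model
reproduces a peak relative activity of 0.39 and a day-2 GTQ of 0.17.
Only those two scalar anchors are meaningful; the curve's fine shape is
an assumption, and quantities that depend on it (e.g. hour-by-hour
activity) inherit that uncertainty.

## Pharmacokinetics

Dexamethasone and methylprednisolone use linear two-compartment
disposition with analytic bi-exponential (IV bolus) and tri-exponential
(first-order oral absorption) solutions; regimens are exact
superpositions of unit doses, and IV dexamethasone-phosphate doses are
converted to active-drug equivalents by molecular-weight ratio
(392.5/472.4). The free fractions (0.23), oral bioavailability of
dexamethasone (0.59) and molecular weights are reference values.

Prednisone is a prodrug with nonlinear kinetics: a three-state ODE (gut,
plasma prednisone, plasma prednisolone) in which a first-pass fraction
(0.78) of the absorbed dose enters as prednisolone, interconversion and
elimination act on free concentrations, and free prednisolone follows a
saturable transcortin + linear binding equilibrium solved in closed form
(`prednisolone_free_fraction()`). The saturable binding makes free
exposure supra-linear in dose and keeps the total
prednisolone/prednisone ratio inside the reported 2.7-10 band at all
simulated times.

**Caveat:** the clearances, volumes, absorption and interconversion
constants are literature-plausible placeholders (flagged `placeholder`
in the packaged CSVs) because the authoritative supplementary values
were not available for transcription. Regimen-level GTQ numbers should
be read as structural, not quantitative, predictions; the model-level
quantities (steady state, reductions, chase, cortisol calibration) do
not depend on them.

## The glucocorticoid transcription quotient

`gr_gtq()` scores a 24-h exposure as the time-average of relative
activity over the second simulated day (burn-in day first):
`GTQ = (1/1440) * integral of fRnGN(t)/rngn_max dt`, a trapezoid on the
output grid (grid-converged to <1e-4 between 1- and 4-min steps). Two
routes are available: exact time-dependent integration, and the analytic
steady state applied pointwise to `G(t)` — accurate whenever forcing
varies slowly against the receptor cycle; for the diurnal cortisol curve
the two agree to better than 0.001. `gr_regimen_gtq()` composes the PK
engine with the GTQ (for prednisone regimens the active ligand is
prednisolone), and `gr_table4()` tabulates the packaged regimen battery.

## Problem sizes and runtime

Everything is desk-scale: a two-day trajectory at 1-min output is a
5-state stiff ODE solved in well under a second; a chase run is ~0.2 s;
a full time-dependent cortisol GTQ ~1.4 s; the 22-row regimen table a
few seconds. The full test suite runs in under a minute.
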