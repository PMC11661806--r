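# grpkpd

Simulator for a seven-state kinetic model of glucocorticoid receptor
(GR) trafficking between cytoplasm and nucleus, coupled to drug
pharmacokinetics, with a command-line interface for comparing dosing
regimens by their *glucocorticoid transcription quotient* (GTQ).

The receptor cycles through free cytoplasmic (`Rc`), loosely bound
(`RcG`), tightly bound (`RcGt`), imported (`RnGt`), activated /
DNA-binding-competent (`RnGN`), free nuclear (`Rn`) and loosely bound
nuclear (`RnG`) states. Ligands differ only in two equilibrium
dissociation constants (`Kc`, `Kn`); six first-order rate constants
(`k1`–`k6`) are shared. The package provides:

- the analytic steady state and its high- and very-low-concentration
  Michaelis–Menten reductions (`gr_steady_state()`, `mm_high()`,
  `mm_low()`, `kn_from_kmt()`);
- stiff time-dependent integration under arbitrary free-concentration
  forcing, including a two-species labeled/unlabeled cold-chase variant
  (`gr_simulate()`, `gr_chase()`);
- pharmacokinetic models: linear two-compartment for dexamethasone and
  methylprednisolone (analytic superposition), nonlinear
  prednisone/prednisolone interconversion with saturable transcortin
  binding (`gr_free_concentration()`, `prednisolone_free_fraction()`);
- a calibrated synthetic diurnal free-cortisol profile
  (`gr_cortisol_profile()`);
- GTQ regimen scoring and a packaged regimen comparison table
  (`gr_gtq()`, `gr_regimen_gtq()`, `gr_table4()`);
- a CLI (`inst/cli/grpkpd`, or `gr_cli()` from R) emitting deterministic
  CSV outputs.

See `vignette("methods")` (source in `vignettes/methods.Rmd`) for model
derivations, numerical choices and the documented derived-vs-printed
discrepancies; `gr_validation_report()` recomputes the whole
derived-versus-reference battery at runtime.

## Worked example

Steady state at the nocturnal nadir free-cortisol concentration:

```r
library(grpkpd)
gr_steady_state("cortisol", G = 1.45)
#> <gr_state> G = 1.45 nM, Rtot = 1
#>     Rc    RcG   RcGt   RnGt   RnGN     Rn    RnG
#> 0.0080 0.0002 0.0077 0.0120 0.0600 0.9112 0.0009
#> fRnGN = 0.06004, nuclear fraction = 0.9841
```

Even at 1.45 nM the receptor is already 98 % nuclear, and the activity
relative to the infinite-dose maximum (`rngn_max()` = 0.8065) is
0.06/0.8065 = 0.074 — about 2.6 times the naive Michaelis–Menten
estimate `1.45/(50+1.45)` = 0.028, the model's central pharmacological
point at low concentrations.

The two closed-form reductions:

```r
mm_high("dexamethasone")
#> <gr_mm> high regime: Vmax = 0.8065, Km = 5 nM, denominator constant = 31
mm_low("dexamethasone")
#> <gr_mm> low regime: Vmax = 0.04011, Km = 0.0008021 nM, denominator constant = 24.93
```

Steady-state dose response and nuclear localisation:

```r
gr_dose_response("dexamethasone", G = c(0.01, 0.1, 1, 5, 50))
#>    G_nM      fRnGN relative_activity nuclear_fraction
#> 1  0.01 0.03847044        0.04770335        0.9183113
#> 2  0.10 0.05387856        0.06680941        0.9842212
#> 3  1.00 0.16167163        0.20047282        0.9924476
#> 4  5.00 0.41214444        0.51105911        0.9957084
#> 5 50.00 0.73302401        0.90894977        0.9992145
```

Cold-chase competition (100 nM labeled ligand for 100 min, then a
200-fold unlabeled excess):

```r
ch <- gr_chase("dexamethasone")
gr_chase_halftime(ch)
#> [1] 18.3124
```

GTQ of endogenous cortisol under the packaged synthetic diurnal curve,
and of a prednisone regimen:

```r
gr_gtq("cortisol", profile = gr_cortisol_profile())
#> GTQ = 0.170  (synthetic diurnal cortisol; time-dependent; day window [1440, 2880] min)
gr_regimen_gtq(gr_regimen("prednisone", 20, "q.d.", "oral"))
#> GTQ = 0.421  (prednisone 20 mg oral q.d.; steady-state; day window [1440, 2880] min)
```

From the shell:

```sh
Rscript inst/cli/grpkpd gtq --drug methylprednisolone --dose 320 \
  --schedule qd --route IV --out mp320.csv
Rscript inst/cli/grpkpd table4 --out regimen_table.csv
Rscript inst/cli/grpkpd validate --out validation.csv
```

## Caveats

- The PK clearances, volumes, absorption and interconversion constants
  are literature-plausible placeholders (flagged in
  `inst/extdata/gr_pk_*.csv`); regimen-level GTQ values are structural,
  not quantitative, predictions. The free fractions (0.23), oral
  dexamethasone bioavailability (0.59) and molecular weights are
  reference values.
- The diurnal cortisol curve is synthetic: only its nadir, peak time,
  peak activity (0.39) and day-2 GTQ (0.17) are calibrated anchors
  (`scripts/calibrate_cortisol.R`).
- The derived reduction constants `VmaxH`, `D`, `VmaxL`, `KmL` differ
  from some printed reference values by 2–27 %;
  `gr_validation_report()` and `gr_consistency_report()` track every
  such comparison rather than patching either side.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "grpkpd", load_package = "installed")'
```

The non-acceptance suite is green. `tests/testthat/test-acceptance.R`
holds one block per acceptance criterion; the blocks asserting the
printed high/low-reduction constants fail honestly (see the vignette's
discrepancy discussion) and are intentionally not patched.

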