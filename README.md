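# tmfret

Distance distributions and conformational energetics from transition
metal ion FRET (tmFRET) measured with frequency-domain fluorescence
lifetimes.

Ligand-gated domains such as the cyclic-nucleotide-binding domain (CNBD)
of CNBD-family ion channels interconvert between resting and active
conformations. tmFRET pairs a long-lived fluorescent donor (e.g. the
noncanonical amino acid Acd, lifetime ~17 ns) with a cysteine-reacted
metal-ion acceptor, so the donor–acceptor distance — and hence the
conformational state — shapes the donor decay through the Förster
equation `E(r) = 1 / (1 + (r/R0)^6)`. Measuring that decay in the
frequency domain (phase delay and modulation ratio versus modulation
frequency, a "Weber plot") and fitting it with Gaussian distance
distributions recovers not just average distances but the *distribution*
of distances, including the fraction of molecules in each state.

The package is aimed at spectroscopists analyzing frequency-domain
lifetime FRET titrations. It provides:

* the forward model from a one- or two-Gaussian distance distribution
  (plus donor-only, background, and timing-offset nuisance parameters)
  to predicted phase/modulation (`predict_dataset()`), and phasor
  coordinates with the universal-circle and chord diagnostics
  (`phasor_coordinates()`);
* weighted chi-square fitting: per-dataset single-Gaussian fits
  (`fit_single_gaussian()`), global two-Gaussian fits that share
  structural parameters across ligand conditions and acceptors while
  the active-state fraction `A2` varies per condition
  (`fit_global_two_gaussian()`), and chi-square profile identifiability
  scans (`profile_parameter()`);
* four-state energetics: `delta_G(P_active)` computes
  `-RT ln(P_active / P_resting)` with bound flags at the 0.01 resting
  floor, `delta_delta_G()` the ligand-coupling energy, `delta3_G()` the
  ionic-strength second difference, plus Hill dose–response fitting and
  mean ± SEM aggregation with Student's t-tests;
* steady-state analysis: efficiency from paired cysteine / no-cysteine
  intensity time courses, unlabeled-fraction correction, and
  weighted-average distances from the inverse Förster equation;
* a fully seeded synthetic-data generator (`generate_fd_study()` and
  friends) emulating the canonical two-acceptor × three-condition study
  design, so the entire pipeline is testable without instrument data;
* Weber-plot CSV, manifest JSON, and distance-distribution table I/O.

## Worked example

Simulate the six-dataset study (two acceptors, R0 = 41.8 and 43.5 Å,
conditions apo/cAMP/cGMP) at its default ground truth, refit it
globally, and convert the fitted state occupancies into free energies:

```r
library(tmfret)

study <- generate_fd_study(study_design(seed = 1))
fit <- fit_global_two_gaussian(study$datasets, n_starts = 3)
round(coef(fit)[1:7], 3)
#>       r1   sigma1       r2   sigma2  A2[apo] A2[cAMP] A2[cGMP]
#>   41.019    4.084   29.576    0.689    0.147    1.000    0.352

state_energetics(fit_A2(fit))
#>   condition  P_active         dG dG_bound        ddG ddG_bound
#> 1       apo 0.1467303  1.0425413    FALSE         NA        NA
#> 2      cAMP 1.0000000 -2.7211912     TRUE -3.7637325      TRUE
#> 3      cGMP 0.3522335  0.3607844    FALSE -0.6817569     FALSE
```

The generating truth was `r1 = 40.9`, `r2 = 29.5` Å with `A2` =
0.12/1/0.34: the refit recovers the two state distances to a few tenths
of an Ångström and the occupancies to a few hundredths at realistic
instrument noise (0.2° phase, 0.004 modulation). `dG` is the
resting-to-active free energy in kcal/mol at 298 K; the cAMP row is
flagged as a bound because the fit pinned `A2` at 1, so its energy is
"more favorable than" −2.72 kcal/mol given the 0.01 resting floor.
`ddG` is each ligand's coupling energy relative to apo.

Diagnostics:

```r
weber_plot(study$datasets[1:3], fit)   # data and fitted curves
phasor_plot(study$datasets[1:3])       # mixtures inside the universal circle
prof <- profile_parameter(study$datasets, param = "r2",
                          grid = seq(28.5, 30.5, 0.25))
plot(prof)                             # resolved chi-square minimum
```

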