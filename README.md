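# felbind

Analysis toolkit for **alchemical absolute binding free energy (ABFE)
calculations on flexible protein–ligand systems**, built around the
MDM2/MDMX inhibitor benchmark. It is aimed at computational chemists who
already have per-λ-window energy-difference samples (e.g. from GROMACS
decoupling runs) and collective-variable trajectories, and need the
downstream analysis: free energy estimation, restraint corrections,
cycle assembly, the flexibility correction, and benchmarking against
experimental affinities. Running molecular dynamics itself is out of
scope.

## What it computes

**Bennett acceptance ratio (BAR).** For adjacent λ states *j*, *k* with
forward samples ΔU_F = H_k − H_j and reverse samples ΔU_R = H_j − H_k,
the shift constant *C* solves

    Σ_k f(ΔU_R + C) = Σ_j f(ΔU_F − C),   f(x) = 1 / (1 + exp(x/k_BT)),

and ΔG = C + k_BT ln(N_j/N_k). Totals telescope over the λ schedule
(20-window solution leg, 30-window complex leg by default), with
frame-bootstrap standard errors.

**Boresch restraint correction.** The standard-state cost of the
six-point ligand restraint (one distance, two angles, three dihedrals):

    ΔG_restr = RT ln[ 8π²V⁰ / (r₀² sinθ_A0 sinθ_B0)
                      · (K_r K_θA K_θB K_φA K_φB K_φC)^½ / (2πRT)³ ],

gated behind an independent quadrature oracle over the exact
r² dr sinθ dθ dφ measure.

**Thermodynamic cycle.** ΔG°_binding = −ΔG_prot(decouple) +
ΔG_solv(decouple) + ΔG_restr_on(solv).

**Free-energy-landscape (FEL) correction.** A 2-D landscape over
(radius of gyration, RMSD) of the apo receptor,
G(bin) = −k_BT ln(n/n_max); end-state conformations from the decoupling
run are mapped onto it and their mean landscape free energy is added to
the raw estimate — correcting the overbinding caused by the apo state
staying trapped near the holo conformation.

**Benchmarking.** IC50/Ki → ΔG conversion (RT ln c/c°), MAE, RMSE,
Pearson and Spearman metrics, and the shipped 5-complex MDMX and
14-complex MDM2 benchmark tables.

Every estimator is validated against synthetic generators with
closed-form ground truth (Crooks-consistent Gaussian work distributions,
two-basin collective-variable mixtures, rigid-motion toy structures).

## Worked example

Evaluate the MDM2 benchmark before and after the landscape correction:

```r
library(felbind)
run_evaluate(list(dataset = mdm2_benchmark()))
#> <evaluation_report> n = 14
#>   MAE  3.077 kcal/mol
#>   RMSE 3.808 kcal/mol
#>   Pearson  0.389
#>   Spearman 0.314
run_evaluate(list(dataset = mdm2_benchmark(), corrected = TRUE))
#> <evaluation_report> n = 14
#>   MAE  1.953 kcal/mol
#>   RMSE 2.838 kcal/mol
#>   Pearson  0.435
#>   Spearman 0.345
```

The correction drops the mean absolute error from ~3.1 to ~2.0 kcal/mol
and improves both rank correlations — the headline effect of accounting
for receptor flexibility.

A full synthetic ABFE cycle with a known answer:

```r
rest <- boresch_restraint(r0 = 0.3, theta_A0 = pi/2, theta_B0 = pi/2,
                          k_r = 1000, k_thetaA = 10, k_thetaB = 10,
                          k_phiA = 10, k_phiB = 10, k_phiC = 10)
syn <- synthetic_cycle(dg_prot_total = 14, dg_solv_total = 3, rest,
                       sigma = 1, n = 2000, seed = 11)
run_abfe(list(prot_windows = syn$prot_windows,
              solv_windows = syn$solv_windows,
              restraint = rest, n_boot = 100, seed = 11))
#> <abfe_report>
#>   complex leg (decouple):    14.031 +/- 0.045 kcal/mol
#>   solution leg (decouple):    3.008 +/- 0.036 kcal/mol
#>   restraint on (analytic):    7.433 kcal/mol
#>   dG_binding:                -3.590 +/- 0.058 kcal/mol
syn$dg_design
#> [1] -3.566602
```

The estimate lands within one combined standard error of the designed
value. See `vignettes/felbind-methods.Rmd` for the model, the numerical
choices and the validation design.

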