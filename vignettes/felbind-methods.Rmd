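---
title: "Methods: absolute binding free energies with a landscape correction"
author: "felbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute binding free energies with a landscape correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felbind)
```

## The problem

Alchemical absolute binding free energy (ABFE) calculations decouple a
ligand from its environment twice — once in solution, once in the
receptor complex — and close a non-physical thermodynamic cycle:

$$\Delta G^\circ_{\mathrm{binding}} =
  -\Delta G^{\mathrm{prot}}_{\mathrm{elec+vdw+restr}}
  +\Delta G^{\mathrm{solv}}_{\mathrm{elec+vdw}}
  +\Delta G^{\mathrm{solv}}_{\mathrm{restr\_on}}$$

Both decoupling legs are reported as the free energy of turning
interactions *off*, so the printed equation applies with no extra sign
bookkeeping (`assemble_binding_dg()`). For a flexible receptor such as
MDM2, the apo protein sampled at the decoupled endpoint tends to stay
kinetically trapped near the holo conformation, which systematically
overestimates binding strength. The package implements a correction for
this: the end-state conformations are mapped onto a free energy landscape
(FEL) of the independently sampled apo state, and their mean landscape
free energy is added to the raw estimate.

Internal units are fixed throughout: kcal/mol, nm, radians, Kelvin, with
R = 1.98720×10⁻³ kcal/mol/K. Readers convert at the boundary (1 kcal =
4.184 kJ; PDB coordinates Å → nm). A single unit system avoids the silent
mixing of kcal/mol/nm² and kcal/mol/rad² force constants that the
restraint definition invites.

## BAR estimation

The free energy between adjacent λ states is estimated with the Bennett
acceptance ratio. Given forward samples $\Delta U_F = H_k - H_j$ (in
ensemble $j$) and reverse samples $\Delta U_R = H_j - H_k$ (in ensemble
$k$), the shift constant $C$ solves

$$\sum_{k\text{-ensemble}} f(\Delta U_R + C) \;=\;
  \sum_{j\text{-ensemble}} f(\Delta U_F - C),
  \qquad f(x) = \frac{1}{1 + e^{x/k_BT}},$$

after which $\Delta G = C + k_BT\,\ln(N_j/N_k)$ (equal sample counts give
$\Delta G = C$; the identity follows from the detailed-balance property
of the Fermi function and is verified in the tests against an independent
fixpoint iteration and a logistic-regression maximum-likelihood
formulation). Numerical choices:

* the left side minus the right side is strictly monotone in $C$, so the
  root is found by bracketed `uniroot` with tolerance
  `.Machine$double.eps^0.75` and a self-consistency acceptance threshold
  of 10⁻⁸ (per-sample scale), maximum 200 refinement iterations;
* the Fermi function is evaluated through the logistic CDF, stable for
  $|x/k_BT|$ up to several hundred (endpoint windows can reach hundreds
  of kT);
* one-sided exponential averaging (`exp_averaging()`) uses log-sum-exp
  shifting. Note the one-sided estimates bracket BAR *in expectation*
  (opposite Jensen biases), not sample by sample — the test suite
  demonstrates this distinction;
* chained totals are the telescoping sum over adjacent pairs
  (`bar_chain()`), with contiguity of the λ chain enforced;
* standard errors are frame-bootstrap (`bar_stderr()`, resampling with
  replacement within each window and direction, default 200 replicates,
  explicit seed). No decorrelation or subsampling is applied to the input
  series; a stride can be applied upstream if samples are correlated.

The λ schedules of the protocol (`default_schedules()`) are: coulomb
switched off over 0, 0.25, 0.5, 0.75, 1; van der Waals over fifteen
non-uniform windows 0.05–1; the complex leg adds ten bonded-restraint
windows 0.01–1 — 20 solution windows and 30 complex windows in total,
each counted as one λ state.

## Boresch restraint correction

The six-point restraint (one distance $r_0$, two angles, three dihedrals,
harmonic with $U = \tfrac{K}{2}(x-x_0)^2$) holds the decoupled ligand in
the binding site; its standard-state free energy cost is analytic in the
stiff-spring limit:

$$\Delta G_{\mathrm{restr}} = RT\,\ln\!\left[
  \frac{8\pi^2 V^0}{r_0^2 \sin\theta_{A0}\sin\theta_{B0}}\,
  \frac{(K_r K_{\theta A} K_{\theta B} K_{\phi A} K_{\phi B}
  K_{\phi C})^{1/2}}{(2\pi RT)^3}\right]$$

with $V^0$ = 1.6605 nm³ (1 L/mol per molecule). `boresch_dg()`
implements this closed form; `boresch_numeric()` is an independent
oracle that evaluates the restrained configurational integral by
separable composite-Simpson quadrature over the exact measure
$r^2\,dr\,\sin\theta_A\,d\theta_A\,\sin\theta_B\,d\theta_B\,
d\phi_A\,d\phi_B\,d\phi_C$, each 1-D range covering (by default) 8
harmonic standard deviations clipped to the physical domain, with an
automatic refinement check.

Because the quadrature carries no stiff-spring approximation, the two
differ by the Jacobian corrections
$RT\sigma_\theta^2/2$ per angle (from
$\int\sin\theta\,\mathcal N(\theta_0,\sigma^2)\,d\theta =
\sin\theta_0\,e^{-\sigma^2/2}$) minus $RT\ln(1+\sigma_r^2/r_0^2)$ for the
distance. At the protocol's force constants (1000 kcal/mol/nm², 10
kcal/mol/rad²) and $r_0 = 0.3$ nm this residual is 0.031 kcal/mol — small
against every other error source in an ABFE pipeline but nonzero, and it
grows as $RT^2/K_\theta$ for softer restraints (at 0.01 kcal/mol/rad² the
stiff form is off by more than 1 kcal/mol). Exact identities that do not
depend on the stiff limit — $V^0$ doubling shifts the result by exactly
$RT\ln 2$, scaling all six constants by 4 adds exactly $3RT\ln 4$ — are
verified to machine precision.

The protein-side restraint contribution is *not* computed analytically:
it arrives through the bonded λ windows of the complex leg, as in the
simulation protocol.

## Collective variables and the landscape

The FEL is built over two collective variables computed per frame
(`cv_timeseries()`): the mass-weighted radius of gyration and the RMSD
against the first production frame after optimal superposition. The
superposition uses the Kabsch SVD construction with the determinant-sign
correction so reflections are never returned; the fit is mass-weighted
and the reported deviation unweighted by default (the dominant
trajectory-tool convention; both are switchable). Atom selection is
delegated to input preparation: whatever atoms are provided are used.

`build_fel()` histograms the samples on a regular grid (default 100×100,
spanning the sample range padded by one bin width per side) and sets

$$G(\text{bin}) = -k_BT\,\ln\frac{n(\text{bin})}{n_{\max}},$$

so the most populated bin is exactly zero, occupied bins are
non-negative, and empty bins carry *no* value (flagged, never zero). No
kernel smoothing is applied. Two consequences deserve emphasis:

* **The zero point matters.** The correction term averages *relative*
  free energies read off this surface, so it inherits the
  global-minimum-is-zero convention. If the reference were placed
  elsewhere, every correction would shift by a constant. The convention
  adopted here (and flagged prominently) is that corrections are measured
  from the global minimum of the apo landscape.
* **Empty-bin lookups.** End-state conformations can fall in empty bins
  or outside the grid. The default policy substitutes the nearest
  occupied bin (Euclidean distance in bin-index space, deterministic
  column-major tie-break) and warns; a strict `error` policy is
  available.

The correction itself (`correction_term()`, `apply_correction()`)
averages the landscape values of the extracted end-state conformations —
by convention five frames strided evenly over the last 100 ps
(`tail_conformations()`) — and adds the mean to the calculated binding
free energy; its SEM is sd/√n. Uncertainties combine in quadrature by
default. The published MDM2 table's ± column for corrected values is
consistent with *linear* addition of the two errors, so a `"linear"`
option reproduces that convention when wanted.

### Reading a basin gap off the landscape

For validation, the free energy gap between two basins is read from the
landscape by `fel_basin_gap()`. The difference of the two modal-bin
values is conceptually direct but carries Poisson noise of order
$k_BT/\sqrt{n_{\text{peak bin}}}$ — 5–10% of a $k_BT\ln 4$ gap even at
10⁵ samples. The population estimator,
$-k_BT\ln(P_{\text{minor}}/P_{\text{major}})$ over the summed bin counts
of each basin, is exact for basins of matching shape, independent of bin
count, and binomially tight; it is the estimator used in the validation
suite, with the modal-bin value cross-checked at its own noise scale.

## Affinity conversion and benchmark metrics

Experimental IC50 and Ki values are both treated as dissociation-constant
surrogates and converted as $\Delta G = RT\ln(c/c^\circ)$, $c^\circ$ = 1
M, default 298 K (so 1 M maps to exactly zero and 11 µM to −6.76
kcal/mol). The evaluation report (`evaluate_predictions()`) carries MAE,
RMSE, Pearson and Spearman (average-rank ties) plus per-complex errors;
`count_within()` counts predictions inside an inclusive error band.

The shipped benchmark tables (`mdmx_benchmark()`, 5 MDMX complexes;
`mdm2_benchmark()`, 14 MDM2 complexes) reproduce the published summary
statistics from their printed, rounded entries: MDMX MAE 0.816 / RMSE
1.065; MDM2 uncorrected MAE 3.08 / RMSE 3.81 / Pearson 0.389 / Spearman
0.314; corrected MAE 1.95 / RMSE 2.84 / Spearman 0.345. Three
discrepancies in the source tables are surfaced rather than silently
matched: the corrected Pearson computes to 0.435 from the rounded
entries (0.430 was reported, presumably from unrounded intermediates);
one row (3TJ2) prints a corrected value 0.028 kcal/mol away from its own
calculated + correction sum; and direct enumeration finds 9 of 14
corrected predictions within 2 kcal/mol of experiment, not the 11 stated
in prose.

## Synthetic ground truth

Because per-complex ABFE inputs require molecular dynamics, every
estimator is validated against generators with closed-form answers:

* **Crooks-consistent Gaussian work** (`gaussian_work_windows()`):
  forward $\mathcal N(\Delta G + \sigma^2/2k_BT, \sigma)$, reverse
  $\mathcal N(-\Delta G + \sigma^2/2k_BT, \sigma)$. This pair satisfies
  the Crooks fluctuation theorem exactly, so the designed $\Delta G$ is
  the true free energy by construction. Default width σ = 1 kcal/mol
  (≈1.7 kT, a typical per-window overlap for a well-spaced schedule).
* **Two-basin CV mixture** (`two_basin_cv()`): 2-D Gaussian basins at
  (1.10, 0.15) and (1.25, 0.35) nm with σ = 0.015 nm — fluctuation and
  separation scales realistic for a folded ~85-residue domain whose Rg is
  ≈1.1–1.3 nm — and populations summing to 1; the true gap is
  $-k_BT\ln(p_2/p_1)$. Basins closer than 3σ trigger a warning because
  the gap stops being identifiable from histogram populations.
* **Toy structures** (`toy_structures()`): frames are the reference under
  random proper rotations and translations plus fixed-magnitude
  random-direction atomic displacements, so the post-superposition RMSD
  is the designed magnitude (exact in the large-N limit, ±5% at N = 100).
* **Full cycle** (`synthetic_cycle()`): both legs generated with designed
  totals plus the analytic restraint term, so the assembled
  $\Delta G^\circ_{\mathrm{binding}}$ is known exactly.

All generators take explicit integer seeds and restore the global RNG
state on exit.

What the generators deliberately do *not* emulate: time correlation of
MD samples (every frame is independent, so bootstrap errors are
optimistic relative to correlated data), anharmonic work distributions,
water or force-field physics, and multi-basin landscapes beyond two
states. Passing validation therefore demonstrates estimator correctness,
not robustness to correlated or non-Gaussian simulation output.

## Problem sizes and runtimes

The validation suite uses 10⁴ samples per direction for the BAR bias
grid, 10⁵ samples for landscape construction, 2×10³ samples per window
with 100 bootstrap replicates for the 20-seed end-to-end cycle, and
4001-point Simpson grids for the quadrature oracle — sizes at which every
stochastic tolerance sits several standard errors from its threshold
while the whole suite completes in about two minutes.

## Known limitations

* The FEL correction depends on the global-minimum zero convention of the
  apo landscape; a differently normalised landscape shifts all
  corrections by a constant.
* Raw-histogram landscapes have no uncertainty model per bin; SEMs for
  the correction reflect conformational spread only, not histogram noise.
* MBAR-style multi-state estimation, automatic equilibration detection
  and binary trajectory formats are out of scope; inputs arrive as plain
  text (xvg-like, CSV, PDB subset, xyz+mass).
* IC50-to-ΔG conversion assumes the Cheng–Prusoff-free Kd-surrogate
  reading; where a table already provides experimental ΔG values those
  are used verbatim.
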