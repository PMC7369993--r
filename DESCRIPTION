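Package: felbind
Title: Absolute Binding Free Energies with a Free-Energy-Landscape Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for alchemical absolute binding free energy
    calculations on flexible protein-ligand systems. Implements the Bennett
    acceptance ratio (BAR) estimator with self-consistent shift constant,
    the analytical Boresch standard-state correction for six-point ligand
    restraints with a numerical quadrature oracle, assembly of the
    non-physical thermodynamic cycle, mass-weighted collective variables
    (radius of gyration, Kabsch-superposition RMSD), construction of
    two-dimensional free energy landscapes over (Rg, RMSD) and the
    landscape-based correction term for receptor flexibility, conversion of
    experimental affinities (IC50/Ki) to binding free energies, and
    benchmark error metrics (MAE, RMSE, Pearson, Spearman). Ships the
    MDM2/MDMX inhibitor benchmark tables and ground-truth synthetic data
    generators (Crooks-consistent Gaussian work distributions, two-basin
    collective-variable mixtures, rigid-motion toy structures) so every
    estimator can be validated without molecular dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), bio3d, jsonlite, yaml, optparse
Config/testthat/edition: 3
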