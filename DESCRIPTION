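Package: pepforge
Title: Antibody-Interface-Derived Peptide Design and Binding Analysis
Version: 0.1.0
Authors@R:
    person("pepforge", "developers", email = "pepforge@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing peptide inhibitors from antibody-antigen
    interfaces and analysing their binding. Reads and writes PDB structures
    with insertion-code residue numbering, computes solvent-accessible
    surface areas by the Shrake-Rupley and Lee-Richards algorithms, maps
    buried-surface (delta-SASA) interfaces and hydrogen bonds, assembles
    linker-joined peptides from interface segments and generates exhaustive
    single-point mutant libraries, screens variants with Conjoint-Triad
    sequence features and regression models (ridge, random forest, gradient
    boosting, XGBoost-style), selects docked poses by interface burial,
    keeps the MM-GBSA energy-decomposition ledger, and post-processes
    molecular-dynamics trajectories (RMSD, RMSF, radius of gyration, SASA
    and hydrogen-bond series, PCA, free-energy landscapes). A synthetic-data
    module generates toy complexes, pose ensembles, affinity corpora and
    trajectories with known ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
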