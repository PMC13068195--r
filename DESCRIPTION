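Package: fragscreen
Title: Grid Free-Energy Fragment Screening and Hit Triage for HIF Inhibitor Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a grid free-energy (FragMap) based
    virtual screening pipeline for dual HIF-1/HIF-2 inhibitor discovery:
    Boltzmann transformation of solute occupancy grids into grid free-energy
    FragMaps, ligand grid free-energy (LGFE) scoring with Monte-Carlo
    simulated-annealing pose refinement, fragment hotspot detection and
    binding-site selection, pharmacophore hypothesis enumeration and
    RMSD-threshold library screening, drug-likeness triage with Morgan
    fingerprint clustering, and the downstream quantitative endpoints of such
    a campaign (dose-response IC50, 1:1 binding Kd, trapezoidal AUC,
    delta-delta-Ct fold change, tumor volume, sequence conservation, and
    complete-response meta-analysis). Synthetic-data generators with known
    ground truth exercise every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    bio3d,
    minpack.lm,
    ChemmineR,
    ChemmineOB,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
LinkingTo: Rcpp
SystemRequirements: OpenBabel (obabel on PATH) for SMILES import and 3D embedding
Config/testthat/edition: 3
RoxygenNote: 7.3.3
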