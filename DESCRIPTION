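Package: jmlipid
Title: Protein-Lipid Interaction Fingerprints for Receptor Tyrosine
    Kinase Juxtamembrane Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for protein-lipid interactions of
    single-pass receptor juxtamembrane (JM) regions in anionic membranes:
    per-residue lipid contact matrices, occupancy fractions and residence
    times, unit-area-normalized lateral radial distribution functions,
    occupancy density maps, clustering propensities and family-wide
    positional aggregation across the human receptor tyrosine kinase
    family. Includes a seeded two-dimensional Brownian-dynamics membrane
    emulator (WCA excluded volume plus screened-Coulomb attraction between
    basic residues and anionic lipid headgroups) that generates synthetic
    trajectories with the annular-shell statistics the analyses assume, so
    the full pipeline is testable without coarse-grained MD data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
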