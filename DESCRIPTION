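Package: mdlens
Title: Residue Networks, Hydrogen-Bond Fingerprints and Free-Energy
    Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("mdlens", "developers", email = "mdlens@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for protein molecular dynamics
    trajectories centred on inhibitor binding studies: hydrogen-bond
    detection and occupancy fingerprinting between two systems,
    per-frame residue interaction networks decomposed into communities
    by Girvan-Newman edge-betweenness removal with RGB co-membership
    projection, superposition-based RMSD/RMSF and dynamic
    cross-correlation maps, and a free-energy layer converting
    inhibition constants to binding free energies, closing
    thermodynamic cycles, and estimating alchemical free-energy
    differences with Zwanzig, BAR and MBAR estimators. Ships synthetic
    trajectory generators with planted ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
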