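Package: trajdescr
Title: 3D Molecular Descriptors from LAMMPS Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-molecule, per-frame 3D molecular descriptors directly
    from LAMMPS input data files (atom style "full") and text dump trajectories.
    Reconstructs unwrapped molecular geometries under periodic boundary
    conditions and evaluates six descriptor families widely used in
    quantitative structure-property relationship (QSPR) modelling: 3D
    topology/connectivity indices, geometric shape and size descriptors,
    GETAWAY descriptors from the molecular influence (leverage) matrix,
    charged partial surface area (CPSA) descriptors over a solvent-accessible
    surface area engine, WHIM weighted principal-axis statistics, and
    RDF/3D-MoRSE/spatial-autocorrelation descriptors, plus system density.
    Writes one descriptor table per molecule and ships seeded synthetic
    fixture generators so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
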