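Package: lyotraj
Title: Freeze-Drying Simulation Pipeline Operators and Trajectory Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses the five-stage lyophilization protocol of a
    protein formulation (room temperature, freezing, primary drying, secondary
    drying, reconstitution): box definition, monomer replication, excipient
    loading and counterion neutralization, hexagonal-ice placement, bulk-water
    stripping, residual-water selection and re-solvation, together with the
    structural observables used to judge formulation stability (RMSD, radius
    of gyration, solvent-accessible surface area and its non-polar ratio,
    beta-sheet content, hydrogen-bond counts, inter-monomer contact statistics
    and heatmaps, oligomer sizes, excipient-contact occupancy and
    aggregation-prone-residue difference maps). Includes deterministic
    synthetic-fixture generators so every operator is testable without
    molecular-dynamics runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    pracma,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
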