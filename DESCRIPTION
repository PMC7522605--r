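Package: ifacedyn
Title: Interface Dynamics Analysis for Antibody-Antigen Complexes
Version: 0.1.0
Authors@R:
    person("Interface", "Dynamics Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    two-partner protein complexes, built around the antibody/antigen interface.
    Reads multi-model PDB trajectories, constructs binding-scenario variants
    (segment truncation and rigid 90-degree rotation away from the partner),
    detects interfacial hydrogen bonds under geometric criteria and computes
    their per-replica survival ratios with max/average/standard-deviation
    summaries, measures buried solvent-accessible surface area, pairwise
    switched-cutoff interaction energy, partner-aligned segment RMSD, and
    water accessibility, and aggregates per-frame metrics across replicas
    with significance testing. A deterministic synthetic-trajectory generator
    with known ground truth makes every stage testable without MD output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
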