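Package: pocketmd
Title: Protein-Ligand Pocket Interactions from Docking Poses and MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Geometric detection of six protein-ligand interaction classes
    (hydrogen bonds, water bridges, pi-pi stacking, pi-cation, hydrophobic,
    ionic) on single poses and multi-model PDB trajectories, with binding
    pocket extraction, chemistry perception (donors, acceptors, aromatic
    rings, charged groups), contact tables, trajectory RMSD/RMSF/occupancy
    statistics, and bookkeeping for externally computed interaction-energy
    decompositions (SAPT0 components, FMO2/PIEDA pair energies, total
    interaction energy sums, thermodynamic-cycle enthalpies). Includes a
    synthetic-data generator that plants interactions at exact geometries,
    builds Bernoulli-occupancy trajectories, and emits energy tables with
    known totals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
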