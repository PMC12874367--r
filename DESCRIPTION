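Package: cagedyn
Title: Conformational Dynamics Analysis of Pd2L4 Lantern Metallacages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for lantern-shaped [Pd2L4]4+
    metallacages. Perceives the cage topology (Pd nodes, four bitopic
    ligands, central aromatic rings, endo-facing atoms) from XYZ/PDB
    structures, partitions molecular graphs into symmetry-equivalence
    classes and averages partial charges within classes, computes the
    inter-ligand angle theta between central-ring planes along trajectories
    and classifies frames as closed, semiopen or open, integrates state
    densities into residence-time populations, computes Boltzmann conformer
    populations of energy-labelled ensembles, locates minima and conformer
    energy gaps on 2D (d1, d2) relaxed-scan surfaces, and compares relative
    single-point energies across methods. Includes seeded synthetic
    generators for idealized cages, state-switching trajectories, multi-well
    scan surfaces and noisy charge tables, plus a command-line workflow
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    bio3d,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
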