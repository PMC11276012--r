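Package: mdpolar
Title: Polar-Contact Classification, Water-Bridge Lifetimes and Bitopic
    Linker Design from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis of protein-ligand polar contacts in
    molecular dynamics trajectories of G-protein-coupled receptors, with
    emphasis on the class A sodium pocket. Provides per-frame detection of
    hydrogen bonds, salt bridges, single-water bridges and hydrophobic
    contacts; a three-way per-frame classification of ligand engagement of a
    focal residue (direct, water-mediated-only, none); intermittent
    indicator autocorrelation with integral and exponential-fit correlation
    times and replica-level error estimates; bridging-water identity
    exchange accounting; static-structure geometry (Ballesteros-Weinstein
    residue resolution, Kabsch superposition, displacement metrics); and an
    aliphatic linker-length proposal for bitopic ligand design. Includes a
    synthetic trajectory generator with two-state Markov ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
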