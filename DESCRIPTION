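Package: tmdimer
Title: Conformational Analysis of Transmembrane Helix Dimerization in
    Coarse-Grained Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify the dimerization of membrane-embedded
    alpha-helical transmembrane domains (TMDs) from coarse-grained bead
    trajectories. Provides per-frame helix geometry (inter-helical
    centre-of-mass distance, tilt and crossing angles, kink angles,
    crossing-point localization), dimer-state detection, Shrake-Rupley
    buried surface area, residue contact maps, per-residue RMSF,
    Boltzmann-inversion free-energy profiles with replicate averaging,
    GROMOS (Daura) RMSD clustering with Kabsch superposition, and a
    rule-based X-shaped/V-shaped/parallel packing-mode classifier.
    Includes a deterministic system builder reproducing standard
    two-helix starting orientations in a membrane slab, a membrane
    composition bookkeeper, and a Brownian-dynamics two-helix generator
    for synthetic trajectories with controllable association, tilt and
    packing behaviour. Reads and writes GRO, PDB, DCD and a documented
    plain-text trajectory format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
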