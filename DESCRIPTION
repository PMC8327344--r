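Package: lipidsite
Title: Lipid Interaction Site Analysis for Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of lipid-protein interactions at the transmembrane
    surface of pentameric ligand-gated ion channels from molecular dynamics
    style trajectories: per-residue lipid headgroup contact frequency
    profiles with five-fold subunit averaging, time-averaged lipid occupancy
    density grids with OpenDX export, binding-site stability via
    reference-helix Kabsch superposition and lipid headgroup RMSD, and
    cation-pi interaction geometry (choline-to-aromatic-centroid distances).
    Includes a self-contained overdamped-Langevin membrane generator with
    planted, headgroup-charge-dependent binding wells for validation, and
    concentration-response analysis (four-parameter logistic fits, EC50
    fold shifts, fluorination-plot regression, Welch's t-test from summary
    statistics) for the accompanying electrophysiology.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    minpack.lm,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
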