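Package: gatemech
Title: Conformational Mechanics of Membrane Transporters: GNM Hinges,
    Gating Metrics, and Trimer Geometry Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the conformational mechanics of
    neurotransmitter sodium symporters and related membrane transporters.
    Builds Gaussian network models (GNM) on C-alpha networks, decomposes
    the Kirchhoff matrix to obtain slow collective modes, residue
    fluctuations and cross-correlations, and locates global hinge regions
    from the sign structure of the slowest eigenvectors. Computes per-frame
    gating observables from trajectories: centre-of-mass distances between
    gating residue pairs, chi1 side-chain rotamer angles with circular
    state classification, gate-closure times, RMSD series and plateau
    detection, and pooled multi-run histograms. Filters candidate
    three-fold-symmetric trimer assemblies by cylindrical symmetry,
    intracellular exposure of the termini, and interfacial tryptophan
    anchoring, ranking clusters by size. A seed-deterministic synthetic
    data module generates coarse-grained fixtures (two-domain hinge
    structures, two-state gate trajectories, rotamer trajectories with
    prescribed circular distributions, and exact or perturbed C3 trimers)
    so every stage is testable without molecular dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
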