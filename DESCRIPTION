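Package: c3bind
Title: Design and Binding Analysis of C3-Symmetric Ligand-Binding Trimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational design of C3-symmetric helical-bundle
    homo-trimers that bind a three-fold-symmetric small molecule (amantadine)
    on the shared symmetry axis, and for the quantitative characterization of
    the resulting binding equilibrium. Includes a PDB-subset structure model
    with C3 symmetry operations and an ideal-geometry amantadine builder;
    Crick-parameterized generation of two-ring C3 helical bundles; grid-search
    placement of the ligand along and about the symmetry axis; a symmetric
    simulated-annealing rotamer packer with layer rules and a simplified
    physical energy; geometric hydrogen-bond network detection; structural
    evaluation (Kabsch superposition, Shrake-Rupley solvent accessibility,
    pocket composition, water-mediated hydrogen-bond paths, sequence
    observables); and binding analysis (two-state Bloch-McConnell lineshape
    simulation and titration fitting with bootstrap errors, fraction-bound
    dissociation-constant bounds, thermofluor melt-curve processing).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
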