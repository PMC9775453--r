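Package: cycloscope
Title: Geometric and Physicochemical Analysis of Cyclodextrin Inclusion
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural and physicochemical characterisation
    of cyclodextrin host-guest inclusion complexes.  Reads small-molecule
    crystal structures (CIF, PDB) and text trajectories (multi-model PDB,
    XYZ), expands crystallographic symmetry, and annotates beta-cyclodextrin
    macrocycles with per-atom chemical roles.  Computes the standard
    macrocycle conformational descriptors (O4 heptagon planarity and
    ellipticity, glucose tilt angles, gg/gt/tg primary-rim rotamers,
    Cremer-Pople ring puckering, the approximate sevenfold cavity axis),
    host-dimer and guest orientation geometry, crystal packing mode, and
    hydrogen-bond and close-contact lists.  Implements Higuchi-Connors
    phase-solubility analysis (profile typing, apparent 1:1 stability
    constant Kc and complexation efficiency CE with delta-method
    uncertainties) and MM/GBSA binding free-energy bookkeeping from
    per-frame component tables.  Parametric generators build idealised
    cyclodextrins, host-guest assemblies, trajectories, phase-solubility
    datasets and energy tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
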