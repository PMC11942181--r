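Package: condstat
Title: Structural Analysis of Microphase-Separated Biomolecular Condensates
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for slab-geometry simulations of diblock
    elastin-like polypeptide (ELP) condensates. Builds (V-P-G-V-G)n-(V-P-G-X-G)n
    diblock topologies at several resolutions, reads and writes GRO/PDB
    coordinate frames and pressure-tensor tables, and computes the standard
    condensate observables: chain clustering and slab re-centering, per-species
    density profiles and central-block enrichment, inter-chain contact maps,
    block-resolved and guest-environment radial distribution functions, radii
    of gyration with an ideal-chain reference, hydrogen-bond detection and
    water hydrogen-bond density, Shrake-Rupley solvent-accessible surface area
    and relative solvent accessibility, surface tension from pressure-tensor
    anisotropy, and correlation of condensate properties with hydrophobicity
    scales. Includes synthetic-data generators with known ground truth
    (morphology-controlled condensate slabs, planted hydrogen-bond fixtures,
    freely jointed chain ensembles, pressure series) for validating every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
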