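Package: cifchem
Title: Chemical Entity Perception from Small-Molecule Crystallographic Data
Version: 0.1.0
Authors@R:
    person("Rokas", "Kazlauskas", email = "rokas.kazlauskas@example.org",
           role = c("aut", "cre"))
Description: Derives chemical entities (bonds, bond orders, Kekule forms,
    formal charges and metal-coordination conventions) from small-molecule
    crystallographic descriptions. Reads a restricted CIF dialect, restores
    stoichiometrically correct molecular ensembles by crystallographic
    symmetry expansion with positional-disorder resolution and polymer
    detection, assigns chemical structures with a six-step perception
    algorithm driven by Gaussian bond-length distribution classes, validates
    the result with six molecular-geometry checks and six entry-level data
    quality tests, and writes MDL Molfile V2000/V3000, SDF, TSV/DWAR tables
    and three-scope SMILES. Metal-ligand contacts are recorded as zero-order
    coordination bonds that are ignored in formal-charge bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
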