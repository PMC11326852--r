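Package: xtalformer
Title: Patterson-to-Density Map Prediction with a 3D Patch Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for posing and studying the crystallographic phase
    problem as a supervised learning task in space group P1. Generates
    synthetic peptide fragments with idealized geometry, derives electron
    density and Patterson maps from structure factors on regular grids,
    builds standardized per-residue partial-structure maps, and fits a
    hybrid 3D convolution / transformer regression model in which
    Patterson-map tokens attend one-way to partial-structure tokens.
    Includes evaluation by map Pearson correlation and resolution-binned
    mean phase error, plus readers and writers for PDB coordinates,
    CCP4/MRC maps and plain-text reflection lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
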