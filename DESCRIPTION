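Package: molforge
Title: Batch Generation of 3D Molecular Models from SMILES for AR and Teaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns SMILES line notation (single strings, comma-separated
    batches, or CSV files) into colored triangle-mesh models of molecules in
    building-kit, ball-and-stick, or space-filling style. Batches are laid
    out side by side in a labeled scene and exported to AR-capable and
    cross-platform 3D formats (USDZ, glTF/GLB, zip of USDZ, OBJ, STL) or
    rendered to PNG with a built-in software rasterizer. Conformers are
    embedded by seeded distance geometry so identical input reproduces
    identical models while different seeds show different conformations.
    Includes a small offline trivial-name dictionary and a fixture generator
    for large synthetic batches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ChemmineR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
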