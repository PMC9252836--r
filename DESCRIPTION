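Package: rnatangle
Title: Detection and Classification of Entanglements in RNA 3D Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies, classifies, and reports entanglements of structural
    elements (loops, dinucleotide steps, single strands) in RNA tertiary
    structures. Reads PDB and PDBx/mmCIF files, derives canonical base pairs
    geometrically, assigns pseudoknot orders by iterative extraction of
    maximum non-crossing pair sets, partitions the structure into open and
    closed elements at the core level and at each pseudoknot order, spans
    triangle meshes on closed elements, detects punctures by segment-triangle
    intersection (Moller-Trumbore), and classifies lasso and interlace
    arrangements such as L(S), L(S..) or L&D. Includes a synthetic-structure
    generator with provable ground truth for testing, and a command-line
    driver for batch screening of RNA 3D models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
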