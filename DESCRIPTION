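Package: devFEA
Title: Developmental Finite-Element Analysis of Musculoskeletal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linear-static finite-element analysis of developing
    musculoskeletal structures from labeled tetrahedral meshes. Reads and
    writes Gmsh MSH, legacy VTK and Abaqus INP meshes with region tags and
    named node sets; builds anatomically anchored muscle load vectors from
    attachment areas, physiological cross-sectional area and specific
    tension; assembles and solves the four-node tetrahedron elasticity
    system with reaction recovery, von Mises and principal stresses;
    removes anterior-posterior sliding against the fixed contact surface by
    rescaling one muscle pair; and assembles ontogenetic series reports of
    bite force, neurocranium force, stress hotspots and three-axis muscle
    orientation angles. Includes deterministic synthetic phantoms (bars,
    paired-lobe pharyngeal-jaw geometry, allometric growth series) for
    validation without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
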