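Package: bifacet
Title: Design Toolkit for Bifaceted Pseudo-Dihedral Protein Nanomaterials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing bifaceted (Janus-like) protein nanomaterials
    with pseudo-dihedral symmetry. Docks cyclic pseudosymmetric rings along
    their shared symmetry axis, identifies and asymmetrizes the resulting
    dihedral interface by emitting biased and multistate sequence-design
    specifications, filters candidate designs with negative-design rules over
    structure-prediction confidence metrics, and defines extended or
    reoriented target architectures for backbone-diffusion tools. Includes a
    synthetic building-block generator producing idealized pseudosymmetric
    heterotrimers and five-fold crown rings, rigid-body and superposition
    primitives, and a bead-colocalization statistic. Heavy machine-learning
    inference (sequence design, structure prediction, backbone diffusion) is
    interfaced through files, not re-implemented.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
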