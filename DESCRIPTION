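Package: phore
Title: Structure-Based Consensus Pharmacophore Modeling and Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives consensus pharmacophore models from ensembles of aligned
    protein-ligand crystal structures and uses them for virtual screening.
    Perceives interaction-filtered pharmacophore features (hydrogen-bond
    donors and acceptors, hydrophobes, positive and negative ionizable
    points) from each complex, clusters features pooled across complexes,
    retains clusters recurring above a statistical-frequency threshold, and
    assembles the retained features with receptor-derived excluded-volume
    spheres into a screenable model. Multi-conformer small-molecule
    libraries are mapped onto the model with a geometric fit value, ranked,
    and filtered by Lipinski druglikeness and key-residue interaction
    criteria. Includes seeded synthetic fixture generators (toy complexes
    with planted interactions, planted-active screening libraries) so the
    whole pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
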