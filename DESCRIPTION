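Package: qpharm
Title: Pharmacophore Elucidation in Protein Binding Sites by Deep
    Q-Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects candidate pharmacophore feature points in a protein
    binding site with a multilabel 3D convolutional network over voxelized
    atom-type densities, assembles an optimal feature subset into a
    pharmacophore with a deep geometric Q-learning agent whose reward is
    the F1 score of the pharmacophore in virtual screening, and provides
    the screening engine (correspondence enumeration, Kabsch alignment,
    receptor exclusion) together with enrichment metrics and seeded
    synthetic fixtures so the whole loop runs at desk scale without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    pROC,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
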