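Package: confdyn
Title: Conformational Dynamics Analysis for Engineered Enzyme Ensembles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies how active-site conformational dynamics change when
    an NADH oxidase is engineered to accept truncated noncanonical
    nicotinamide cofactors. Provides multi-model PDB ensemble input/output
    and atom selection, loop-flexibility RMSD via Kabsch superposition,
    hydride-transfer donor-acceptor distance occupancy classification,
    backbone-dihedral principal component free-energy landscapes with
    K-Means conformational state assignment, degenerate-codon library
    coverage statistics, and a synthetic ensemble generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
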