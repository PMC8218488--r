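Package: moietyrank
Title: Rank Submolecular Moieties of a Bound Ligand by Binding Destabilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies "malicious" submolecular moieties of a lead molecule
    bound to a target protein from molecular dynamics trajectories. Ligand-protein
    contact matrices are aggregated by force-field atom subtypes, enriched with a
    temporal-dynamism channel, embedded with an ensemble of convolutional
    variational autoencoders, and density-clustered with HDBSCAN. Per-subtype
    cluster-size series are compared against a whole-molecule RMSD reference
    clustering with cosine-similarity and average-difference metrics, producing a
    ranking of moieties most likely to destabilize binding. Includes a
    free-energy-to-relative-potency calculator for verifying suggested
    modifications, and a synthetic-data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
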