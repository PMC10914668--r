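Package: apclust
Title: Receptor-Affinity Fingerprint Taxonomy of Antipsychotics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds receptor-affinity fingerprints for antipsychotic drugs
    from published Ki binding records, clusters drugs by fingerprint
    similarity (probabilistic PCA imputation of missing affinities, Pearson
    correlation graph, Louvain community detection), characterizes the
    resulting clusters pharmacologically and clinically, and quantifies how
    well any categorization scheme predicts clinical effect profiles via
    leave-one-drug-out partial least squares prediction with a permutation
    null. Includes a synthetic-data generator with planted cluster structure
    so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
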