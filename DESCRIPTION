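Package: subtypePCA
Title: Hierarchical Molecular Subtype Classification by Supervised PCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns expression profiles to hierarchically nested molecular
    subtypes by supervised principal component analysis of pre-defined
    classifier genes. An unknown sample is merged into a labeled reference
    cohort, projected into principal-component space, and assigned at each
    level of a subtype hierarchy to the nearest subtype centroid under a
    variance-weighted Euclidean distance. Assignment confidence is reported
    as normalized inverse-distance membership probabilities, and a
    relative-distance score (distance in units of the subtype's own
    dispersion) flags outlier profiles. Includes GCT/TSV expression matrix
    input and output, a seeded synthetic-cohort generator with nested
    cluster structure, leave-one-out and train/test evaluation harnesses,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
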