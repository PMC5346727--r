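Package: genpnp
Title: Genetic and Epigenetic Network Identification and Principal Network
    Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs genetic and epigenetic networks (GENs) from matched
    mRNA expression, miRNA expression and promoter methylation profiles.
    Per-gene transcription models with methylation-attenuated transcription
    factor activity and miRNA repression, and per-protein bilinear
    interaction models, are identified by sign-constrained least squares;
    false-positive candidate edges are pruned by backward elimination under
    the Akaike information criterion.  Core subnetworks are extracted by
    principal network projection: singular value decomposition of the
    combined network matrix, projection of each node onto the leading
    singular directions, and thresholding of the projection distances.
    Includes a synthetic-data generator drawn exactly from the structural
    models so that identification, pruning and projection can be validated
    against a known ground truth, stage-to-stage comparison statistics
    (differential methylation and miRNA calls, edge-polarity consistency,
    projection-distance correlation), an enrichment-table filter, and
    target-specific drug selection from a local drug-gene interaction table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
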