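Package: compareScreen
Title: COMPARE-Style Pharmacogenomic Analysis of Drug Screening Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links tumor-cell drug response (log10 IC50 profiles across an
    NCI-60-style cell line panel) to transcriptome-wide mRNA expression.
    Implements pairwise cross-resistance correlation of compound potency
    profiles, the COMPARE procedure that ranks every probe by the Pearson
    correlation of its expression profile with a compound's log10 IC50
    vector (standard and reverse candidate lists), complete-linkage
    hierarchical clustering of cell lines over the candidate-gene submatrix
    with z-standardization and a pairwise-available missing-value distance,
    and a chi-squared test of cluster membership against a median-dichotomized
    sensitive/resistant partition. A seeded synthetic-data generator with a
    latent cross-resistance factor and planted correlated genes makes the
    whole pipeline testable without access to screening databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
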