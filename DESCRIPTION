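Package: hrrnet
Title: Highest-Reciprocal-Rank Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds gene co-expression networks from normalized expression
    matrices using the highest reciprocal rank (HRR) of Pearson correlations,
    estimates network-wide significance cutoffs by permutation, extracts
    guide-gene (seed) clusters and Markov-cluster (MCL) modules from
    thresholded networks, scores clusters by hypergeometric GO
    over-representation with Benjamini-Hochberg FDR control, selects the MCL
    inflation parameter by an enrichment-based F-measure, and summarises
    tissue/condition expression specificity per probeset (ESI) and per
    cluster (cESI). Includes a synthetic-compendium generator with planted
    co-expression modules and annotations for end-to-end validation, and a
    condition-aware pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
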