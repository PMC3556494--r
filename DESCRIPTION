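Package: lnscomp
Title: Cross-Species Co-Expression Conservation via Local Network Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies conservation and divergence of gene co-expression
    networks between two species' expression compendia using the Local
    Network Similarity (LNS) statistic: per-dataset Pearson correlation
    matrices are Fisher z-transformed, standardized to N(0,1), averaged
    across datasets, and each ortholog pair is scored by the Pearson
    correlation of its two connection-weight vectors over all other matched
    orthologs. Includes microarray-style preprocessing (coverage filtering,
    KNN imputation, replicate averaging), a randomized-ortholog permutation
    null, condition-specific LNS, Fourier-based periodic-expression calling,
    association of LNS with sequence-divergence features, k-means clustering
    of condition-specific LNS profiles with hypergeometric enrichment, and a
    seeded synthetic-compendium generator with planted divergence for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
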