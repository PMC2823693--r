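Package: epipair
Title: Simulation and Replication-Groups Scoring of SNP-SNP Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study whether replication-groups (min-over-subsets)
    scoring of SNP-SNP interactions reduces false positives relative to
    scoring the whole case-control data set directly. Provides a two-locus
    epistasis genotype simulator (six penetrance models, missing-data,
    genotyping-error, phenocopy and genetic-heterogeneity noise), two
    pairwise interaction scores (information-theoretic interaction gain and
    an HFCC-like best-disease-model chi-square), direct, replication-groups
    and bootstrap aggregation strategies, permutation-based imputation of
    known false interactions, and top-k false-positive evaluation curves
    with theoretical best/worst envelopes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
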