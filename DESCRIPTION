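Package: crossdeg
Title: Cross-Species Overlap Analysis of Differential Expression Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparing transcriptomic plasticity between
    two species from gene-level RNA-seq count matrices. Calls differentially
    expressed genes per species with TMM normalization, negative-binomial
    generalized log-linear models and likelihood-ratio tests; maps genes
    across species by reciprocal best hit from tabular alignment results;
    classifies focal-species DEGs as shared, not plastic in the reference
    species, or unaligned; and tests whether cross-species DEG overlap
    exceeds a permutation null, with a closed-form expectation as an
    analytic cross-check. Includes a two-species negative-binomial count
    simulator with block structure and configurable shared plasticity, a
    TPM-based low-expression filter, classical MDS sample ordination, and
    hypergeometric over-representation analysis of gene lists against GMT
    collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
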