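Package: heterosim
Title: Heterosis Analysis of Stress-Tolerance Phenotypes and Hybrid
    Expression Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting heterosis in F1 populations and
    hybrid-parent trios. Implements membership-function scoring of
    stress-tolerance indices with standard-deviation based tolerance
    grades, mid-parent and high-parent heterosis with one-sample
    significance tests, normalization and moderated differential
    expression testing for RNA-seq count matrices, classification of
    hybrid gene expression into eight additive/dominant/overdominant
    profiles against mid-parent and parental references, hypergeometric
    term over-representation analysis with false discovery rate control,
    and a seeded synthetic-data generator that produces phenotype tables
    and negative-binomial trio count matrices with known ground truth so
    that every stage of the pipeline can be verified end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
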