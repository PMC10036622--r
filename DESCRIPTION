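Package: etnet
Title: Edge-Type Comparison of Mutual-Information Networks from Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers statistical-dependence networks from molecule-by-sample
    omics matrices using B-spline mutual information with permutation tests,
    derives condition-difference ("response") networks with four edge fates,
    categorizes edges by annotation-derived edge types (ETs) with fractional
    multi-label weighting, and compares network states through ET graph
    density, chi-squared histogram distances, net-change rankings, a
    two-sample Cramer-von Mises test, and classical (Torgerson)
    multidimensional scaling. Includes a seeded synthetic-cohort generator
    with planted linear and nonlinear dependencies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
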