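Package: flowInherit
Title: Transfer-Function Analysis of Mitotic Partitioning from
    Flow-Cytometry Dye Dilution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how labelled cellular material (for example
    quantum-dot loaded endosomes) is partitioned between daughter cells at
    mitosis, from paired flow-cytometry fluorescence measurements of one
    population at two time points. A forward transfer-function model maps
    the initial intensity histogram to the later one through a truncated
    two-component Gaussian mixture of splitting ratios, and the inverse
    problem recovers the mean splitting ratio, its spread, and the fraction
    of cells that divided, by seeded global optimization. A Monte-Carlo
    single-cell population simulator provides synthetic data and an
    event-level oracle for the convolution model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
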