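Package: contactzone
Title: Population-Genetic and Phenotypic Analysis of Ecotype Contact Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising contact zones between divergent
    ecotypes typed at codominant microsatellite markers. Implements
    GenePop-format input/output, observed and unbiased expected
    heterozygosity, Hardy-Weinberg tests (chi-squared and Monte Carlo
    exact), Weir-Cockerham theta (F_ST) and Jost's D with locus-bootstrap
    confidence intervals on all, neutral-only or QTL-only marker panels,
    P_ST estimation from one-way variance components with bootstrap
    confidence intervals and P_ST-F_ST comparison, Mendelian simulation of
    F1/F2/backcross cohorts, a plug-in-frequency genotype-class classifier
    with a supervised admixture-proportion purity filter and a
    hybrid-detection power analysis, trait size correction, lateral-plate
    morph classification, spine PCA and genotype-phenotype association
    tests, plus a Balding-Nichols synthetic three-ecotype data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
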