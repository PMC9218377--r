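Package: augtrial
Title: Augmented Block Design Trials and Germplasm Diversity Statistics
Version: 0.1.0
Authors@R:
    person("Trial", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of unreplicated germplasm screening trials laid out in
    augmented block designs. Provides check-based block adjustment of test
    entries, per-location and combined across-location analysis of variance,
    variance components with the derived selection-genetics parameters
    (coefficients of variation, broad-sense heritability, genetic advance),
    Shannon-Weaver diversity indices for qualitative descriptors, Pearson
    correlation, principal component analysis and UPGMA / k-means clustering
    of adjusted trait means, and screening of entries for yield gain over
    checks and grain iron/zinc density. A simulation module generates
    multi-location augmented trials with known variance structure so that
    every stage of the pipeline can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
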