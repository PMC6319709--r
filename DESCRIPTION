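Package: qstkit
Title: Quantitative Trait Differentiation and Neutrality Testing for
    Structured Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting signatures of adaptive divergence in
    common-garden experiments on structured plant populations.  Computes
    microsatellite diversity (unbiased gene diversity) and differentiation
    (Weir-Cockerham theta and Nei GST), squared codominant genotypic
    distances with principal coordinate analysis, and admixture-based
    lineage assignment.  Estimates quantitative trait differentiation
    (QST) from nested population / seed-family variance components via a
    blocked Gibbs sampler or REML, simulates the neutral QST distribution
    expected from molecular differentiation using chi-square sampling
    variance, and performs the posterior QST - neutral-QST difference
    test.  Environment-association tools include soil PCA, trait-
    environment cline models, pairwise QST matrices, and multiple matrix
    regression with randomization (MMRR).  A synthetic-data generator
    (island-model genotypes under partial selfing, nested phenotypes,
    correlated soil gradients) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan,
    lmerTest
Config/testthat/edition: 3
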