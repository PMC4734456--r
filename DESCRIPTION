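Package: microdemog
Title: Demographic Effect Sizes on Gut Microbiota Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies how demographic and health-behavior covariates
    (age, sex, race, body mass index, alcohol and tobacco use) associate
    with gut microbiota diversity in 16S rRNA surveys. Implements
    coverage-standardized alpha-diversity (observed OTU richness and the
    Shannon index, with a frequency-count singleton correction),
    unweighted and weighted UniFrac beta-diversity, batch-adjusted joint
    PERMANOVA with distance-based and adjusted R2 effect sizes,
    permutation F-tests for taxon-level signatures under
    Benjamini-Hochberg FDR control, and a seeded Dirichlet-multinomial
    cohort simulator so the whole pipeline can be validated end to end
    on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Matrix,
    phangorn,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    phyloseq,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
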