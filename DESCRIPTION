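Package: hierQF
Title: Hierarchical Quantitative-Trait and Molecular Differentiation (Q-F) Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers past selection and local adaptation from common-garden
    phenotype data and codominant microsatellite genotypes sampled across a
    hierarchy of phylogeographic regions and populations. Estimates nested
    random-model variance components (ANOVA method of moments and REML),
    converts them to hierarchical quantitative-trait differentiation indices
    Q_RT and Q_SR, runs hierarchical analysis of molecular variance (AMOVA)
    on allele-identity distances with standardized indices F'_RT, F'_SR,
    F'_ST and Hedrick's G'_ST, attaches jackknife-over-populations confidence
    intervals, and classifies each trait and level as under diversifying,
    unifying, or no detectable selection by comparing Q with F'. Also provides
    trait-elevation Pearson correlations with sequential Holm-Bonferroni
    correction, G tests on phenological-state tables, and a design-matched
    synthetic-data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'amova.R'
    'auxstats.R'
    'classify.R'
    'data.R'
    'design.R'
    'hierQF-package.R'
    'io.R'
    'jackknife.R'
    'pipeline.R'
    'qindices.R'
    'simulate.R'
    'standardize.R'
    'varcomp.R'
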