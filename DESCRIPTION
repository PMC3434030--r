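Package: strainarray
Title: Strain-Level Brain Transcriptome Analysis for Affymetrix Expression Arrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probe-level analysis pipeline for comparing brain gene expression
    among inbred or wild-derived fish strains on Affymetrix 3' expression
    arrays. Implements RMA-style preprocessing (convolution background
    correction, quantile normalization, median-polish summarization),
    present/marginal/absent detection calls, expression and interquartile-range
    filters, single-feature-polymorphism (SFP) screening from probe-level
    residuals with permutation-calibrated q-values, gene-wise linear models
    with empirical-Bayes variance moderation and contrasts for strain,
    domestication history and sex, EASE-score category overrepresentation,
    behavioral phenotype scoring with nested fixed-effects ANOVA, and
    qRT-PCR ANCOVA with Tukey pairwise comparisons. Includes a synthetic-data
    generator that plants known expression effects and probe-level
    polymorphisms so every detector can be benchmarked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    car,
    emmeans,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
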