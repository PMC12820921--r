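Package: mrniv
Title: Mendelian Randomisation with Non-Inherited Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Mendelian randomisation with non-inherited variants
    (MR-NIV), which uses the parental alleles an offspring did not inherit to
    instrument parental phenotypes and so estimate socially transmitted
    ("genetic nurture") effects of parents on their offspring. Provides an
    inheritance-resolution engine that classifies each parental allele as
    inherited or non-inherited from trio or duo genotypes and builds weighted
    inherited, non-inherited and proxy genetic risk scores; the estimator
    family for these designs (univariable and multivariable two-stage least
    squares with non-inherited scores, offspring-score-adjusted variants, a
    composite-parent model, Wald ratios with linear or logistic link, and
    weak-instrument-robust summary estimators: debiased IVW, continuously
    updating GMM, a robust profile-likelihood estimator and Q-statistic
    heterogeneity minimisation, including a proxy multivariable wrapper for
    duo data); a family-based simulator of trio genotype transmission with
    configurable assortative mating and confounding; and a Monte-Carlo study
    harness reporting bias, variance, coverage and confidence-interval width
    with Monte-Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
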