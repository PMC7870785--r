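Package: momscreen
Title: Second-Trimester Maternal Serum Screening for Fetal Trisomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiples-of-the-median (MoM) normalization, Gaussian
    likelihood-ratio risk calculation and screening-performance evaluation
    for second-trimester maternal serum aneuploidy screening with four
    analytes (AFP, free beta-hCG, uE3 and soluble HLA-G). Includes a seeded
    simulator for correlated lognormal marker cohorts parameterized by
    per-group log10 MoM means, standard deviations and correlations, group
    summary statistics (medians, log10 MoM moments, pairwise correlations,
    Mann-Whitney tests), posterior risk scoring from prior odds and
    multivariate Gaussian likelihood ratios, and evaluation via ROC curves
    with DeLong confidence intervals, Youden-index cutoffs, predictive
    values, detection rate at a fixed false-positive rate and multivariate
    logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, MASS, jsonlite, pROC
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Classification
RoxygenNote: 7.3.3
Collate:
    'markers.R'
    'ScreeningCohort-class.R'
    'MedianCurve-class.R'
    'GroupParams-class.R'
    'simulate.R'
    'mom.R'
    'stats.R'
    'risk.R'
    'eval.R'
    'pipeline.R'
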