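Package: psiloconn
Title: Crossover Pharmaco-fMRI Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for randomized placebo-controlled crossover
    pharmaco-fMRI experiments in rodents, built around a 44-region
    bihemispheric parcellation with a 12-region default mode network (DMN)
    subset. Implements framewise-displacement scrubbing with spline
    interpolation, confound regression and band-pass filtering; Fisher-z
    region-of-interest connectivity and voxel-wise global brain connectivity;
    the network-based statistic with exchange-block permutation inference;
    weighted graph analysis with proportional thresholding, degree-preserving
    null models and small-world propensity; DMN connectivity and sample
    entropy; and permutation-based mixed between-within ANOVA, Spearman
    correlation with t-transform, and cluster-extent correction. A seeded
    synthetic-cohort generator emulates a two-session psilocybin/saline
    crossover design in an alcohol-relapse (ADE) rat model so that every
    stage of the pipeline is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
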