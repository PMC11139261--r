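Package: connectomeAge
Title: Brain-Age Monotonicity and Functional Connectivity Analysis for
    rsfMRI Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether resting-state functional connectivity
    changes monotonically with age. A linear support-vector machine is
    trained on balanced samples from two extreme age groups and asked to
    classify subjects of intermediate, unseen ages; the per-age percentage
    classified as aged is smoothed with a sliding window, summarised by a
    linear trend and a Spearman rank correlation, and mapped to one of
    three aging-trajectory hypotheses. Signed supra-threshold connection
    counts (positive, negative, total) are summarised per age decade and
    sex with Welch t-tests against the youngest group, with site and
    arousal-state filtering and threshold-sensitivity analyses. A synthetic
    connectome-cohort generator (Fisher-z edge model with age drift,
    age-dependent variance and sex-modulated effects) makes the whole
    pipeline runnable and testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'binning.R'
    'classifier.R'
    'connectivity.R'
    'connectomeAge-package.R'
    'fc_stats.R'
    'io.R'
    'monotonicity.R'
    'simulate.R'
    'utils.R'
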