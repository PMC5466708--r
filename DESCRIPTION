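Package: phosphoCensus
Title: Estimating the Total Size of Phosphoproteomes from Overlapping
    Detection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate the total number of phosphoproteins and
    phosphorylation sites in a proteome from many overlapping
    high-throughput detection experiments. Implements saturation-curve
    fitting of cumulative non-redundant versus redundant identifications
    under an exponential recovery model with an optional linear noise
    term, closed-population capture-recapture via loglinear models
    (M0, Mt, Chao's Mh and Mth) with AIC model selection, the two-list
    Petersen estimator, noise injection with downward adjustment of
    estimates, jackknife resampling over experiment subsets, Jaccard
    overlap quality control, experiment-order robustness perturbations,
    and a synthetic detection-matrix generator with known ground truth
    for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
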