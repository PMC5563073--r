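Package: axodyn
Title: RNA Granule Dynamics, Local Translation and Branch Remodeling in
    Axon Time-Lapse Imaging
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@axodyn.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of RNA granule trafficking and docking,
    axonal protrusion dynamics, arbor complexity, fluorescence recovery
    after photobleaching (FRAP), and dwell-map colocalization statistics in
    time-lapse fluorescence imaging of developing axon terminals. Provides
    docking detection with randomized-site and randomized-follow controls,
    motility classification and speed/density estimation, branch and
    filopodium scoring, the axon complexity index, FRAP normalization with
    single-exponential and quadratic fits compared by the extra
    sum-of-squares F test, the fluorescence variation index (FVI) hotspot
    statistic, and Costes-style block-scramble null distributions for masked
    Pearson correlation. A stochastic generator of ground-truth-annotated
    synthetic axon time-lapse data (granule tracks, protrusion events,
    rendered image stacks, FRAP series) supports parameter-recovery
    validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
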