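Package: perisim
Title: Simulation and Analysis of Static Automated Perimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulated visual-field testing and statistical analysis
    of perimetric data. Implements a machine contract (initialize, query, set
    background, present, close) with a simulated observer following a
    cumulative-Gaussian frequency-of-seeing model; adaptive threshold
    procedures (Bayesian ZEST, 4-2 dB staircase, Full Threshold, method of
    constant stimuli with psychometric-function fitting); whole-field test
    orchestration with a growth pattern over Voronoi neighbor graphs;
    normative-model fitting from healthy cohorts with total-deviation,
    pattern-deviation and probability maps; pointwise linear regression and
    the PoPLR permutation test for progression; and Voronoi-based plots for
    regular and irregular test-location grids. A synthetic-data module
    generates healthy cohorts and longitudinal series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
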