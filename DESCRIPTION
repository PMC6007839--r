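Package: fluoroperm
Title: Corneal Epithelial Permeability to Fluorescein by Multi-Drop Ocular Fluorometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of corneal epithelial permeability to fluorescein (Pdc)
    measured with a confocal spot fluorometer and a multi-drop protocol: a
    dilute probe drop characterizes first-order tear clearance (single
    exponential, zero plateau), concentrated loading drops drive measurable
    stromal accumulation, and permeability follows from a closed-form
    equation scaling the probe-drop area under the curve to the loading
    drops, with an instrument correction factor for the focal-diamond /
    tear-film geometry. Includes tear-trace nonlinear least-squares fitting
    with quality control, cohort table reading and per-eye permeability
    recomputation, Monte Carlo uncertainty propagation with Weibull and
    normal parameter distributions, and synthetic-data generators (tear
    traces, whole cohorts, inner-filter-effect depth scans) for end-to-end
    testing against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
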