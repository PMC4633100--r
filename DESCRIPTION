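Package: wlcAFM
Title: Simulation-Assisted Persistence-Length Analysis of AFM-Imaged DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure the bending stiffness (persistence length) of short
    DNA molecules from scanning atomic-force-microscopy (AFM) height images.
    Includes a Monte-Carlo simulator of two-dimensional equilibrium worm-like
    chains, a mock-AFM renderer (tip-shape grey-scale dilation, pixelation,
    Gaussian background noise, plane flattening), a skeleton-based contour
    tracer with Freeman chain-code length estimation, a simulation-based
    calibration of the tracer's contour-length bias, and the calibrated
    inversion of the 2D worm-like-chain end-to-end relation with segment
    pooling, bootstrap uncertainties and scale-dependence trend tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
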