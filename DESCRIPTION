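Package: DeBias
Title: Decoupling Global Bias from Local Interactions in Paired
    Cell-Biological Variables
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Separates the two sources of coupling between paired
    cell-biological measurements: a global bias that shapes both marginal
    distributions (for example cell polarity aligning two cytoskeletal
    networks) and a genuine local interaction between matched observations.
    The observed alignment distribution is compared against a resampled
    null, in which the pairing is destroyed by independent resampling of
    the marginals, using the one-dimensional Earth Mover's Distance to a
    uniform reference. This yields a global index GI = EMD(uniform,
    resampled) and a local index LI = EMD(uniform, observed) - GI. Supports
    co-orientation data (axial angles) and pixel- or object-based
    co-localization data (fluorescence intensities), provides the matching
    synthetic-data generators, automatic histogram bin selection by the
    Freedman-Diaconis rule, a subsampling permutation test for comparing
    conditions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: ImageAnalysis, StatisticalMethod, Visualization
RoxygenNote: 7.3.3
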