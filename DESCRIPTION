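Package: aggrekin
Title: Nucleation-and-Growth Kinetics of Amyloid Self-Assembly from ThT and DLS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying amyloid aggregation mechanisms from
    complementary biophysical assays. Implements a two-population
    nucleation-and-growth kinetic model with primary nucleation, fibril
    elongation and fibril-surface-catalysed secondary nucleation; joint
    least-squares estimation of the rate products from thioflavin-T (ThT)
    progress curves and dynamic light scattering (DLS) intensity
    distributions; per-curve sigmoid fitting for half-time (t50) and growth
    rate (v50) descriptors; forward modelling and regularized inverse
    Laplace transform (CONTIN-style) of DLS autocorrelation functions;
    transmission electron microscopy (TEM) particle morphometry with
    oligomer/fibril shape classification and Feret-diameter statistics;
    dissociation constants from native mass-spectrometry abundances; and
    seeded synthetic-data generators emulating each assay for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
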