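Package: chromdev
Title: Computer-Assisted Method Development for Reversed-Phase Liquid
    Chromatography of Unknown Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers the components of an unknown mixture from a small
    campaign of screening gradient runs recorded with second-order detectors
    (DAD-UV or full-scan MS), using multivariate curve resolution by
    alternating least squares (MCR-ALS) with SIMPLISMA initialization and
    non-negativity/unimodality constraints. Extracted component spectra are
    correlated across runs into a component catalog with retention-time
    assignments and alert diagnostics, per-component linear solvent strength
    retention models are fitted, and gradient elution programs are optimized
    by multi-objective differential evolution with Pareto selection. Includes
    a synthetic-campaign generator with known ground truth, Hoke-sized
    screening designs, and a stepwise gradient retention simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    pracma,
    minpack.lm,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
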