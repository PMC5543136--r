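Package: targetkin
Title: Global and Target Analysis of Time-Resolved Difference Absorption Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Compartmental kinetic modelling and variable-projection fitting
    of time-resolved difference-absorption matrices from ultrafast pump-probe,
    pump-dump-probe and flash-photolysis spectroscopy. Provides exact
    Gaussian-IRF-convolved solutions of first-order rate networks with
    branching and instantaneous dump-pulse population transfer, sequential
    (EADS), parallel (DADS) and scheme-based target (SADS) global analysis,
    spectral equal-bleach constraints, photoisomerization quantum-yield
    estimation with delta-method errors, and a synthetic-data generator
    emulating channelrhodopsin-like photocycle datasets from femtoseconds
    to seconds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    deSolve,
    pracma,
    withr
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
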