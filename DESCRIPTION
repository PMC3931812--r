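Package: fretbind
Title: Quantitation of Calmodulin Binding from FRET Biosensor Titrations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of ratiometric FRET biosensor titrations used to locate
    and characterize calmodulin-binding domains in membrane receptors.
    Computes fractional biosensor responses and dynamic ranges from
    donor/acceptor emission intensities with per-addition dilution correction,
    fits apparent dissociation constants with hyperbolic or ligand-depletion
    (quadratic) single-site isotherms, calibrates free calcium from a
    co-measured fluorescent indicator, fits Hill calcium-sensitivity curves,
    and decomposes biphasic calcium-response curves into two complex species.
    Includes a synthetic titration generator that emulates the
    spectrofluorometric assays (dilution schedules, chelator-buffered free
    calcium, indicator response, measurement noise) for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
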