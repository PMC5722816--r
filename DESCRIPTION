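Package: tafit
Title: Global and Target Analysis of Femtosecond Transient Absorption Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic modelling of time-resolved difference-absorption
    matrices from pump-probe experiments on pigment-protein complexes.
    Provides analytic solutions of first-order compartmental schemes
    convolved with a Gaussian instrument response, sequential-scheme global
    analysis yielding evolution- and decay-associated difference spectra
    (EADS/DADS), compartmental target analysis with variable projection of
    species-associated difference spectra (SADS) under zero-region and
    cross-dataset linking constraints, a library of light-harvesting-complex
    kinetic schemes, a synthetic pump-probe data generator with known ground
    truth, and carotenoid end-ring dihedral analysis of coordinate ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    deSolve,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
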