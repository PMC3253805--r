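Package: branchcycles
Title: Periodicity Analysis of Branching Events on Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests for orbital-scale (Milankovitch) periodicity in the
    branching times of dated ultrametric phylogenies. Extracts
    branching-event ages from chronograms or node-age tables, bins them
    into discrete time series, and applies serial-dependence statistics
    (autocorrelation and partial autocorrelation with large-sample
    significance), harmonic analysis (single-frequency Fourier
    coefficients, the full periodogram, and Fisher's exact g-test for
    the largest ordinate), and a permutation-based bivariate comparison
    of harmonic amplitudes between clade groups. Includes construction
    of fossil-interval calibration points and an inhomogeneous-Poisson
    ("Court Jester") branching simulator with sinusoidally forced
    speciation rates at eccentricity-band periods for type-I-error and
    power validation. Ships the dated node ages of the East
    Mediterranean blind mole rats (Spalacidae) as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
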