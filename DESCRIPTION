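Package: rotjet
Title: Conformational Analysis of Jet-Cooled Molecules by Broadband Rotational Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the conformational analysis of molecules studied by
    broadband microwave (rotational) spectroscopy in supersonic jets.
    Provides Watson A-reduced semi-rigid asymmetric-rotor energy levels,
    electric-dipole transition simulation with direction-cosine line
    strengths, peak picking and R-branch progression detection in broadband
    spectra, iterative line assignment with weighted least-squares fitting
    of rotational and quartic centrifugal-distortion constants, conformer
    identification against quantum-chemistry predictions via
    rotational-constant scale factors, Boltzmann population and
    collisional-relaxation modelling for jet expansions, rotational
    constants and dipole components from Cartesian geometries, and
    evaluation of the Shallenberger-Acree-Kier glucophore (sweetness
    triangle) distance criteria. Includes seeded synthetic-data generators
    emulating measured line lists and broadband spectra so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
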