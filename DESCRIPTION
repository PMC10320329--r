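Package: morphowrinkle
Title: Morphoelastic Simulation of Wrinkling in Growing Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static morphoelastic finite-element simulation of a stiff
    film growing on a compliant substrate, as in the cuticle of petal epidermal
    cells. The deformation gradient is decomposed multiplicatively into an
    elastic response and a diagonal growth tensor (F = A G), the layers are
    compressible neo-Hookean, and equilibria are followed through the wrinkling
    bifurcation by Newton continuation over a pseudo-time growth schedule.
    Includes turgor-bulged and multi-cell base boundary schedules, volumetric
    (3D) scenarios, surface-pattern quantification (onset time, amplitude,
    wavelength, including an exact crest-distance map on curved bases), and an
    analytic film-on-substrate stability oracle for critical wavelength and
    strain scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
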