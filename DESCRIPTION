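Package: radstab
Title: Modelling Ionizing-Radiation Dose Effects on Physicochemical
    Properties of Pharmaceutical Solids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-empirical modelling of how absorbed ionizing-radiation dose
    (gamma or high-energy electron beam) alters physicochemical properties of
    a crystalline drug substance, developed around metoprolol tartrate.
    Provides Bragg-law wavelength extraction from X-ray powder diffraction
    peak tables, a sigmoid-modulated quadratic intensity-dose model with an
    optimized-dose root, exponential dose-relaxation models for pH and
    melting point, linear mutual-correlation links between property pairs,
    bounded nonlinear least-squares fitting with explicit convergence
    contracts, and seeded synthetic-data generators for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'models.R'
    'synthetic.R'
    'fitting.R'
    'doseresponse.R'
    'diffraction.R'
    'cli.R'
    'io.R'
    'fixtures.R'
    'radstab-package.R'
    'serialize.R'
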