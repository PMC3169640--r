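Package: chemios
Title: Composable Chemiosmotic Rate Law for Electron Transport Chain Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for modeling mitochondrial electron transport chain (ETC)
    complexes with a composable chemiosmotic rate law that factors the flux of
    an energy-transducing complex into saturation, redox-state and
    thermodynamic-force terms, with proton-motive-force coupling and slippage
    transformations. Includes a three-complex (CI-CIII-CIV) pathway simulator
    with shared carrier pools, progress-curve parameter estimation mirroring
    standard spectrophotometric assay protocols, reference implementations of
    the Korzeniewski (linear force-flux) and Beard (mass-action) complex I
    rate equations for comparison, metabolic control analysis (flux control
    coefficients and threshold curves), and a seeded synthetic assay-data
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
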