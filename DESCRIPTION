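Package: USWIcrack
Title: In Silico Ultrasonic Shear-Wave Imaging of Soft-Tissue Cracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates ultrasonic shear-wave imaging (USWI) of thin
    blood-filled cracks (lacerations) in a liver-mimicking elastic medium,
    and detects the crack without reconstructing an elasticity map. The
    pipeline couples a heterogeneous finite-difference shear-wave solver, a
    2-D linear-scattering radio-frequency speckle synthesizer,
    phase-sensitive baseband correlation speckle tracking, a [k, omega]
    directional filter that separates incident from reflected wave
    components, and Sobel edge detection on the accumulated reflected-wave
    amplitude. Ships analytic crack geometries (straight, curved, slim)
    with ground-truth edge positions for quantitative error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'USWIcrack-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'phantom.R'
    'wavesim.R'
    'rf.R'
    'tracking.R'
    'directional.R'
    'detect.R'
    'pipeline.R'
    'show-methods.R'
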