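Package: spheroidgrowth
Title: Continuum Simulation of Confined Tumor Spheroid Growth with Stress
    Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Radially symmetric continuum simulator of tumor spheroid growth
    as an incompressible neo-Hookean elastic tissue in an Eulerian frame.
    Elastic stresses are tracked through an adaptive reference map that
    relaxes toward the current configuration at a tunable rate, yielding
    Maxwell-like stress relaxation. Growth is limited by a screened-diffusion
    nutrient profile and regulated by mechanochemical feedback: compressive
    stress drives water efflux and inhibits volume growth, and crowding
    inhibits cell division. Supports external confinement by a neo-Hookean
    gel or applied hydrostatic pressure with timed release events, a moving
    free boundary, steady-state detection and parametric sweeps, plus
    grid-search calibration against radius and density observations with
    corrected-AIC model comparison and a synthetic-observation generator for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports: stats, utils, graphics, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
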