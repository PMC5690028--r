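Package: emmcup
Title: Energy-Minimization Correction of Cupping Artifacts in Cone-Beam CT
Version: 0.1.0
Authors@R:
    person("Emmcup", "Maintainers", email = "emmcup@example.org",
           role = c("aut", "cre"))
Description: Removes cupping artifacts from reconstructed cone-beam CT
    slices by decomposing each slice into a piecewise-constant tissue image
    and a smooth additive bias field expanded in a low-degree polynomial
    basis. The decomposition minimizes a least-squares energy by alternating
    exact closed-form updates of the basis coefficients, the tissue mean
    intensities, and a hard tissue-membership map. Ships uniformity metrics
    (cupping magnitude tau_cup, root-mean-square contrast, a
    contrast-to-noise ratio convention, line profiles), a synthetic phantom
    generator with known ground truth for validation, simple lossless image
    I/O (raw float with JSON sidecar, CSV), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
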