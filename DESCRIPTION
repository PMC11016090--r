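Package: mclsim
Title: Through-Focus Visual Strehl Simulation of Multifocal Contact Lenses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns radial power profiles of multifocal contact lenses into
    wavefront phase maps and through-focus Visual Strehl (TF-VS) curves by
    Fourier optics, and fits temporal-multiplexing programs (time
    coefficients over 0.1 D focus steps) for optotunable-lens visual
    simulators so that the program's simulated TF-VS reproduces the lens's
    theoretical TF-VS. Includes bench-validation criteria (peak shift and
    RMSE of the through-focus curves), a synthetic lens-design generator
    emulating aspheric center-near and concentric-ring archetypes,
    depth-of-focus and partial-correlation comparison statistics, and a
    small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
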