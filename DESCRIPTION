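Package: aidar
Title: Single-Breath Nanoparticle Lung Deposition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-breath measurements of nanoparticle
    deposition in the distal lung (airspace dimension assessment, AiDA).
    Processes pneumotachograph flow traces and condensation particle counter
    concentration traces into loss-corrected particle recovery, fits the
    exponential decline of recovery with residence time, and normalizes
    recovery to a reference residence time. Includes the semi-empirical
    instrument penetration model with calibration fitting, slip-corrected
    Brownian diffusion physics (Cunningham slip factor, Stokes-Einstein
    diffusion, diffusional deposition kernels for spheres and laminar tubes),
    a simplified forward deposition simulator, and a synthetic-data generator
    that emulates the instrument and a subject cohort with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
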