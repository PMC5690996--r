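Package: setupcorr
Title: Off-Line Correction Protocols for 6DoF Patient Setup Errors in
    Image-Guided Radiotherapy
Version: 0.1.0
Authors@R:
    person("Radiotherapy Physics", "Tools", email = "physics@example.org",
           role = c("aut", "cre"))
Description: Simulation and evaluation of off-line six-degrees-of-freedom
    (6DoF) setup-error correction protocols for fractionated radiotherapy on
    robotic couches. Implements the no-action-level (NAL), extended NAL
    (eNAL) and eNAL++ protocols alongside daily-online and no-correction
    baselines, the decomposition of population residuals into systematic
    (Sigma) and random (sigma) components per rotation/translation axis,
    rotation-to-displacement geometry under IEC 61217 axis conventions, a
    synthetic treatment-course generator, and a command-line pipeline
    comparing protocol accuracy against imaging workload.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
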