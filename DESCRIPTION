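Package: cvsid
Title: Subject-Specific Lumped-Parameter Cardiovascular Models from
    Minimal Hemodynamic Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of a six-chamber lumped-parameter model of
    the cardiovascular system (time-varying elastance ventricles with
    septal and pericardial interaction, passive arterial and venous
    chambers, pressure-gated valves) together with a staged iterative
    proportional-gain identification scheme that fits subject-specific
    model parameters from a minimal set of clinically available
    measurements: mean, amplitude and maximum ascending gradient of the
    aortic and pulmonary artery pressures, stroke volume, global end
    diastolic volume, and the mitral and tricuspid valve closure times.
    Includes beat-level waveform feature extraction, a virtual-subject
    generator emulating endotoxic (septic) shock for end-to-end testing,
    and Bland-Altman style agreement statistics for validating identified
    models against independent measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
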