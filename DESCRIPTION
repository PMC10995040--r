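Package: coroflow
Title: Personalized Aortic Pressure Waveforms and Hyperemic Coronary
    Flow-Perfusion Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds personalized four-phase aortic root pressure waveforms
    from routine clinical measures (heart rate, brachial pressures, left
    ventricular mass), derives the effective coronary driving pressure for
    non-contracting flow models, maps resting hemodynamics to adenosine
    hyperemia through interquartile-cleaned linear regressions, solves a
    three-compartment Darcy model of myocardial perfusion on a voxelized
    slab with a blinded resting-inflow calibration, and computes FFR on a
    Poiseuille resistive surrogate of the coronary tree coupled one-way to
    the perfusion model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
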