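Package: dermadiff
Title: Transdermal Diffusion Models for Skin-Plus-Sensor Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analytic one-dimensional Fickian diffusion models of the combined
    skin-plus-sensor system underlying wearable transdermal biosensors.
    Provides closed-form series step responses for concentration-type
    (Neumann), ideal flux-type (Dirichlet) and finite-sensitivity Robin-type
    sensor boundary conditions, a Sturm-Liouville eigensolver for the Robin
    problem, an independent Crank-Nicolson finite-difference verification
    solver, response-timescale metrics (leading-exponential and
    integrated-intercept), and amperometric calibration arithmetic for
    classifying real sensors (including the transdermal ethanol case study)
    by their dimensionless sensitivity relative to skin permeability.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
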