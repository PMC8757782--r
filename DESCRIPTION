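Package: rfablate
Title: Virtual Power-Controlled Irrigated Radiofrequency Catheter Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale virtual model of power-controlled irrigated
    radiofrequency (RF) catheter ablation of cardiac tissue. Couples a
    quasi-static electric potential solve with Pennes-type bioheat time
    stepping on an axisymmetric finite-element mesh, with
    temperature-dependent tissue properties, contact-force indentation of
    the electrode tip, reduced convective models for saline irrigation and
    blood-flow cooling, 50 degree Celsius isotherm lesion metrics (depth,
    width, depth-at-width, volume), and steam-pop / charring safety
    monitors. Includes a factorial study pipeline for high-power
    short-duration (HPSD) protocol characterization, a repeated-application
    analysis exploiting thermal latency, cooling calibration against
    reference lesions, and analytic verification fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
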