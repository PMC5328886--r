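Package: abdopv
Title: Abdominal and Airway Pressure-Volume Curve Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the relationship between additional
    intra-abdominal volume and intra-abdominal or peak airway pressure in
    stepwise abdominal inflation experiments. Fits two candidate
    pressure-volume equations (the four-parameter Venegas sigmoid and a
    three-parameter exponential elastic-recoil model) by bounded nonlinear
    least squares, selects the better model by root-mean-square error,
    applies Boyle's-law correction to injected gas volumes, estimates
    abdomino-thoracic pressure transmission by pooled regression, derives
    abdominal compliance, and tabulates the predicted effect of adding a
    fixed volume at each grade of intra-abdominal hypertension. Includes a
    synthetic-cohort generator emulating stepwise balloon-inflation
    experiments in pigs for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
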