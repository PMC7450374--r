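Package: glucodetect
Title: Infection-Induced Deviations in Self-Recorded Type 1 Diabetes Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting infection-induced deviations in
    self-recorded type 1 diabetes data (blood glucose, insulin, carbohydrate
    intake).  Provides event-log import and validation, uniform hourly/daily
    resampling with cubic-spline glucose imputation, trailing moving-average
    smoothing and insulin-to-carbohydrate ratio construction, weekly
    infection-vs-reference deviation statistics, adaptive Gaussian kernel
    density estimation with a diffusion plug-in (improved Sheather-Jones)
    bandwidth selector, a seeded behavioral glucose-insulin simulator of
    patient-years with infection episodes, and a prototype per-individual
    infection ("microevent") detector with alarm statuses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
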