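Package: cooldose
Title: Cooling-Dose Metrics and U-Shaped Dose-Response Analysis for
    Selective Cerebral Hypothermia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes cooling-dose metrics (AUC34/AUC30 degree-minutes,
    temperature nadir, cooling durations) from per-animal brain temperature
    time series, compares injury outcomes between normothermic and
    hypothermia-treated cohorts (Welch's t-test), tests Pearson correlations
    between cooling parameters and outcomes via Fisher's z transform, and
    fits quadratic (U-shaped) dose-response models with studentized
    non-parametric bootstrap confidence intervals on the injury-minimizing
    dose, the concavity, and the slope at zero dose. A synthetic-cohort
    simulator generates temperature curves and outcomes with the statistical
    structure the analysis assumes, so the full pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
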