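Package: tesdose
Title: Dose Standardization for Transcranial Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts individual peak electric-field strength induced by
    transcranial electrical stimulation (tES) from accessible demographic
    and head-morphology predictors, and converts the predictions into
    individualized stimulation currents that standardize the delivered
    dose across a population. Provides montage-specific robust regression
    models (iteratively reweighted least squares with Tukey's bisquare
    weights), montage-agnostic models that scale with inter-electrode
    distance, cross-validated evaluation (adjusted R-squared, NRMSE,
    Brown-Forsythe/Levene variance tests, partial Spearman correlations),
    grey-matter E-field summarization (95th-percentile peak, focality,
    IQR-fence outlier rejection), and a synthetic cohort generator so the
    whole pipeline is testable without restricted-access imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car
Config/testthat/edition: 3
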