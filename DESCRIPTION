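Package: dietvalid
Title: Biomarker-Based Validation of Dietary Self-Report Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation analysis of short-term dietary self-report instruments
    (online and interviewer-administered 24-h recalls) against recovery,
    predictive and concentration biomarkers. Converts raw biomarker
    measurements (24-h urine collections with PABA completeness checks,
    indirect calorimetry, accelerometry, plasma antioxidants) to reference
    intakes, fits a latent-variable measurement-error model by maximum
    likelihood on the log scale with missing-at-random marginalization, and
    derives attenuation factors, correlations with true usual intake,
    repeat-administration projections, mean percentage differences,
    intraclass correlation coefficients from two-way mixed-effects models
    with method-specific variances, and log-scale Bland-Altman limits of
    agreement. Includes a synthetic-study generator emulating the design of
    a biomarker-based validation study (about 200 participants, three
    occasions two weeks apart) so the whole pipeline is testable without
    participant-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
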