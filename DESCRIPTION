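Package: retbias
Title: Retinotopic Biases in Face Identification: Psychometrics and Neural-Population Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study idiosyncratic retinotopic biases in face
    identification. Generates synthetic trial-level behavioral data from
    location-specific logistic psychometric observers, fits mixed-effects
    logit psychometric models and decomposes points of subjective equality
    (PSE) into population-level values and subject deviations, quantifies
    stability and idiosyncrasy with bootstrap (BCa) statistics, relates the
    retinotopic bias to questionnaire-based familiarity and contact scores
    via nested regressions, and simulates identity-tuned neural populations
    with compressive spatial summation receptive fields decoded by a linear
    classifier to reproduce the mechanism by which the number of tuned
    units and their receptive-field size, but not response gain, control
    the retinotopic bias.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    e1071,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
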