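Package: cariesDRS
Title: Rule-Based Caries Detection from Diffuse Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting dental caries lesions from
    visible/near-infrared diffuse reflectance spectra of tooth enamel.
    Provides reference-based normalization of raw detector counts,
    replicate averaging, Savitzky-Golay smoothing, an exhaustive-search
    classifier built from single-wavelength threshold rules combined by
    disjunction, 4-fold cross-validation with median-rule-set
    consolidation, diagnostic accuracy statistics (PPV, NPV, sensitivity,
    specificity, accuracy), a stain-detection rule with two
    misdiagnosis-relabeling workflows, and a seeded generator of
    synthetic enamel spectra for end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite,
    optparse
Config/testthat/edition: 3
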