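Package: bandstates
Title: Frequency-Band-Resolved EEG Microstate Analysis and Severity Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for narrowband resting-state EEG microstate analysis:
    zero-phase FIR band decomposition, global field power (GFP) peak
    extraction, polarity-invariant modified K-means microstate clustering
    with model selection, canonical A-D template labeling, template
    back-fitting with minimum-duration temporal smoothing, and per-subject
    temporal and Markov transition-probability features. Includes a
    semi-Markov synthetic EEG generator with planted microstate dynamics
    and clinically coupled scores, split-plot group statistics with
    Holm-Sidak post hocs, Spearman clinical-correlation screening under
    Benjamini-Hochberg FDR control, and stratified cross-validated
    single-feature ROC discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
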