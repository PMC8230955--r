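Package: physiograph
Title: Labeled Property Graph Storage and Feature Extraction for Multimodal Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-memory labeled property graph for integrating multimodal
    physiological recordings (EEG, ECG, galvanic skin response) with emotion
    annotations and experiment context. Provides a constraint-checked graph
    store with a shared millisecond timeline, ingestion of timestamp and
    epoch signals from delimited text, per-channel feature calculators
    (Thomson multitaper band power, R-peak derived interbeat-interval and
    heart-rate-variability statistics, skin-conductance peak summaries, and
    histogram-based mutual information between electrode pairs), canonical
    retrieval queries returning tabular multivariate time series, closed-form
    graph sizing estimators, seeded synthetic session generators with known
    ground truth, and export to JSON, GraphML and openCypher scripts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
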