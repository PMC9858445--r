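Package: siamfcn
Title: Few-Shot Siamese Similarity Learning for Multi-Site Functional
    Connectome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies subjects from resting-state fMRI functional
    connectomes collected at heterogeneous imaging sites. Builds dynamic
    functional connectivity features by sliding-window Pearson correlation
    over ROI-averaged BOLD time series, embeds them with a twin (Siamese)
    encoder trained against class prototypes from a designated baseline
    site using a summed per-site pair loss, and evaluates unseen target
    sites by few-shot fine-tuning followed by prototype matching. Includes
    a synthetic multi-site BOLD generator with controllable site
    heterogeneity and group effect so the full pipeline runs without any
    imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
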