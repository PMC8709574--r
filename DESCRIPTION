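Package: hippophen
Title: Behavioral and Neurophysiological Phenotyping for Hippocampal
    Neurogenesis Mouse Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipelines for phenotyping mouse models of altered
    hippocampal neurogenesis: rule-based classification of Morris water maze
    swim paths into search strategies with strategy-block segmentation,
    multi-taper power spectral density and magnitude-squared coherence of
    paired local field potential recordings with frequency-band summaries,
    neurite morphometry on SWC reconstructions (dendritic length, Sholl
    profiles, laminar-reach classification of immature neurons, cell-density
    normalisation), and maturity-day scoring of developmental milestone
    tables. Seeded synthetic-data generators with attached ground truth
    exercise every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
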