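Package: fibreFISH
Title: Quantification of Nascent-Transcript FISH Dots in Syncytial Muscle Fibres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and integrated-density quantification of nascent-transcript
    FISH dots in multinucleated (syncytial) Drosophila muscle fibres, per-nucleus
    co-transcription tabulation for double-FISH experiments, and standardised
    spatial-subdomain classification of dots and nuclei within the DA3 muscle
    frame. Includes a synthetic fluorescence-microscopy generator that emulates
    stochastic ON/OFF transcriptional bursting across syncytial nuclei
    (founder-cell-restricted genes, mutually exclusive programmes, correlated
    joint bursting) with full ground truth, so every pipeline stage is testable
    without microscopy data, and an end-to-end parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Transcription, Visualization, Software
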