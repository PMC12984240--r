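Package: tensorcsbp
Title: Tensor Center-Symmetric Binary Patterns for Explainable Multichannel EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable feature-engineering pipeline for multichannel EEG
    classification. Features are extracted with the tensor center-symmetric
    binary pattern (TensorCSBP): overlapping eight-sample windows, center-symmetric
    channel differences, descending-rank channel transformation, and transition-matrix
    counting. Features are selected by cumulative-weighted neighborhood component
    analysis (CWNCA), classified by a self-organizing k-nearest-neighbor ensemble
    with iterative majority voting (tkNN), and explained through Directed Lobish
    (DLob) symbolic brain-region sequences with entropy, complexity, histogram and
    connectome (transition-matrix) summaries. Includes CSV and EDF readers, a
    synthetic EEG generator with class-dependent spatial asymmetry, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
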