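Package: ethosim
Title: Simulation and Recognition of Hierarchically Structured Behavioral Time-Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generates labeled artificial behavioral time-series built from
    hierarchically structured constituents (state events, point events,
    ordered and unordered composites, pose transitions), the way an
    ethogram decomposes animal behavior. Two supervised sequence
    recognition models are included: a recurrent variational auto-encoder
    with a motif-clustering regularizer, and a masked-span Transformer
    encoder with a recurrent slice-classification head. Per-sample
    confusion matrices at behavior and sub-event level, confusion-group
    summaries and a closed-form single-sample Bayes-oracle classifier
    quantify which behavior dynamics the models can and cannot learn.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
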