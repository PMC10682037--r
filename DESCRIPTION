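Package: repconn
Title: Representational Similarity and Time-Lagged Representational
    Connectivity Analysis for Time-Resolved Neural Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for model-based representational similarity analysis
    (RSA) of time-resolved multichannel neural recordings, and for
    Granger-style representational connectivity analysis (RCA) that
    quantifies direction-specific, time-lagged information flow between
    regions at the level of representational geometry.  Builds model
    dissimilarity matrices from continuous activations (Pearson distance)
    or binary semantic features (cosine distance), derives neural
    dissimilarity time-series from epoched sensor data (sliding-window,
    single-timepoint, and searchlight variants), computes partial Spearman
    RSA time-courses, and performs group inference with sign-flip
    cluster-mass permutation tests and leave-n-out jackknife confidence
    intervals on peak latencies.  Includes a synthetic-data generator that
    injects known representational geometry at known latencies with lagged
    inter-region coupling, so every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
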