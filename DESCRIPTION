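Package: meanet
Title: Spike-Train, Burst and Synchrony Network Analysis for
    Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-electrode array (MEA) spike
    recordings of cultured neuronal networks: threshold spike detection,
    silent-electrode filtering, max-interval burst classification,
    per-electrode spike and burst features with weighted well-level
    summaries and fold changes to baseline, pairwise SPIKE-distance
    synchrony with surrogate-based rate-bias correction, and Louvain
    community detection on the synchrony network. Includes a seeded
    generator of dose-response MEA studies with community-structured
    network bursting for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
SystemRequirements: Python (>= 3.8) with h5py, for HDF5 input/output
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
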