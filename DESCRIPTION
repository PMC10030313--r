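Package: tlmdpc
Title: Time-Lagged Multidimensional Pattern Connectivity for
    Event-Related EEG/MEG Source Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Functional connectivity for event-related, multi-trial
    EEG/MEG source-space data. Estimates cross-validated, ridge-regularised
    vertex-to-vertex linear transformations between the activity patterns
    of pairs of cortical regions at all pairs of latencies, and scores each
    pair of latencies by the explained variance of the transformation,
    averaged over both prediction directions and clamped at zero. Includes
    the unidimensional counterpart in which each region is collapsed to a
    single per-trial summary, k-means-based spatial sub-sampling of
    redundant source vertices with elbow selection of the cluster count,
    construction of latency-by-latency temporal transformation matrices and
    inter-regional connectivity matrices, cluster-based permutation tests
    for contrasting conditions across participants, simulation scenarios
    comparing the multidimensional and unidimensional metrics across
    signal-to-noise ratios, and a point-spread-function leakage index
    calculated from a source-resolution matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
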