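Package: rdcmrel
Title: Test-Retest Reliability of Whole-Brain Regression Dynamic Causal Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates two-session multi-subject BOLD cohorts from a linear
    dynamic causal model with known ground truth, inverts them with
    frequency-domain variational-Bayes regression (classical and sparse
    spike-and-slab variants), computes functional-connectivity baselines
    (Pearson and L1-regularised partial correlations), and quantifies
    group-level consistency, connection-wise ICC(3,1) test-retest
    reliability, and connectome-fingerprinting identification with
    permutation nulls.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
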