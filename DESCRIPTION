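Package: ierp
Title: Intrinsic Event-Related Potentials via CEEMDAN and Cluster-Based
    Permutation Statistics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes per-trial EEG epochs into intrinsic mode functions
    (IMFs) with an improved complete-ensemble empirical mode decomposition
    with adaptive noise (CEEMDAN) using complementary noise pairs, builds
    the full lattice of trial-averaged pure and composite intrinsic
    event-related potential (iERP) modes, and detects condition effects
    with cluster-based nonparametric permutation tests and threshold-free
    cluster enhancement (TFCE) over 2D [mode, time] or 3D
    [channel, mode, time] spaces, using an XOR rule to define neighbouring
    modes. Includes instantaneous-frequency diagnostics, a synthetic-epoch
    generator for validation, plain-text epoch containers, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
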