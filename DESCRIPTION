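Package: vepres
Title: Spatial-Resolution Effects in Virtual-Epileptic-Patient Network Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates epileptic seizure dynamics with the five-dimensional
    Epileptor model on synthetic cortical geometry, both as a high-resolution
    neural field (vertex-level dynamics with a short-range Laplacian coupling
    kernel) and as a low-resolution neural mass (one node per region), projects
    source activity to stereotactic EEG contacts through dipolar and
    inverse-square forward gain models, extracts normalized high-frequency
    envelope data features, and estimates per-region epileptogenicity by
    multi-seed maximum a posteriori inversion of the two-dimensional Epileptor
    reduction. Includes precision-maximizing classification of the recovered
    epileptogenic network against ground truth, catalogue-level experiment
    orchestration, and gain-similarity analysis quantifying how forward-model
    simplification degrades network recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    signal,
    jsonlite,
    methods,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
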