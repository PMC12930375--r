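Package: mdsync
Title: Synchronization and Comparison of Molecular Dynamics Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised synchronization and comparison of molecular dynamics
    (MD) trajectory ensembles. Trajectory frames are converted into
    residue-contact graphs, contacts are pruned by a Shannon-entropy filter,
    frames are embedded as low-dimensional vectors with a Weisfeiler-Lehman
    subtree document-embedding model, replicas are aligned with dependent
    dynamic time warping and summarized by a DTW barycenter with iterative
    outlier pruning, ensembles are compared by Ward clustering of normalized
    DTW distances, and divergence windows are localized with moving-average
    smoothing and PELT change-point detection. A synthetic contact-ensemble
    generator with known ground truth (latent states, monotone time warps,
    condition effects, planted outliers) supports fully offline validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    cluster,
    jsonlite,
    yaml,
    ape,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
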