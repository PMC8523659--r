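Package: cdrflex
Title: Conformational-Ensemble Analysis of Single-Domain Antibody CDR Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for conformational ensembles of single-domain
    (VHH) antibody structures: IMGT-based framework/CDR region annotation,
    framework-superposed per-CDR C-alpha RMSD time series, fraction of native
    contacts (Q-value) with a smoothed logistic contact count, trajectory
    convergence diagnostics (burn-in, post-burn-in stability, half-split
    histogram overlap, outlier-run flagging), and peak-normalized kernel
    density profiles of conformational space with Q-vs-RMSD correlation.
    Includes a deterministic synthetic-ensemble generator with known
    per-region flexibility ground truth for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
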