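Package: netreconfig
Title: Dynamic Network Reconfiguration Analysis for Block-Design Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for studying dynamic reconfiguration of
    functional brain networks during block-design working-memory tasks.
    Builds HRF-weighted block-wise functional connectivity from ROI time
    series, maximizes single-layer modularity (Louvain, best-of-restarts)
    with rewired-network normalization, detects multilayer communities
    across task blocks with condition-dependent interslice coupling
    (generalized Louvain), and summarizes partition ensembles into module
    allegiance matrices with permutation-normalized recruitment and
    integration of large-scale systems. Includes signal-detection d-prime
    behavioral scoring, a synthetic-data generator with planted community
    structure for ground-truth validation, and a config-driven study
    orchestrator with simple group/session contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
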