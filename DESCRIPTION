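Package: basinselect
Title: Energy-Landscape Basin Decomposition and Machine-Learning Decoy
    Selection for Template-Free Protein Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects near-native decoys from large template-free structure
    prediction ensembles by decomposing the decoy energy landscape into
    basins of attraction around local minima of a nearest-neighbor graph,
    ranking basins with Pareto-dominance and graph features, and purifying
    the top basins with a two-phase gradient-boosted regression procedure
    (ML-Select). Also provides the four ranking baselines the method is
    compared against (size, size+energy, Pareto rank, Pareto rank+count),
    purity-based evaluation metrics over merged top-x basin groups, Friedman
    rank tests with a step-down post-hoc ladder, and a seeded synthetic
    multi-funnel ensemble generator so the full benchmark protocol runs
    without external decoy sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    bio3d,
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
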