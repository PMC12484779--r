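Package: edgesem
Title: Semantic Creativity Metrics, Semantic-Network Percolation and
    Edge-Centric Brain Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational machinery for studying how mental imagery relates
    to creative writing through semantic memory and brain network dynamics.
    Provides text-derived creativity scores from word embeddings (global
    semantic distance over sliding windows and divergent semantic
    integration over pairwise cosine distances), semantic-network
    construction from word-vector correlations with percolation-based
    robustness analysis including Gaussian-noise and link-shuffling nulls,
    edge-centric functional connectivity from parcellated BOLD time series
    with overlapping edge-community detection (normalized entropy and
    community-similarity maps over brain networks), a statistical battery
    (Spearman correlations with FDR control, percentile-bootstrap
    mediation, paired and one-sample t tests with Cohen's d,
    Kruskal-Wallis with epsilon-squared and Dwass-Steel-Critchlow-Fligner
    post hoc tests), and seeded synthetic-data generators with planted
    ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
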