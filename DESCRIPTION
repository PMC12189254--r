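Package: dosepath
Title: Multi-Dose RNA-Seq Differential Expression, Dose-Consistency
    Filtering, and Topology-Based Pathway Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for multi-dose bulk RNA-seq experiments in
    which several concentrations of a compound are each contrasted
    against a shared control. Provides negative-binomial per-dose
    differential expression with Benjamini-Hochberg correction, a
    three-criterion dose-consistency filter that retains genes whose
    dysregulation persists and trends coherently across increasing
    doses, hypergeometric over-representation analysis with
    cross-product odds ratios, and a topology-based signaling pathway
    impact analysis (perturbation accumulation over signed gene-gene
    edges) applied per dose across a hierarchical pathway tree. A
    negative-binomial simulator with labeled dose-response archetypes
    and planted gene-set enrichment supplies ground truth for testing
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
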