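Package: connscreen
Title: Dual Expression and Orthology Screen for Candidate Neural
    Connectivity Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a two-pronged screen for genes encoding candidate
    axon-guidance and synaptic-connectivity labels in the developing brain.
    Strategy one clusters per-gene temporal expression-density profiles
    across developmental ages with multi-restart k-means, sweeps the number
    of clusters to assess hierarchical stability, derives consensus protein
    localisation calls from external predictor evidence, and tests
    cluster-by-category enrichment with Pearson chi-square statistics under
    Bonferroni correction, funnelling enriched clusters into a candidate
    list of extracellular proteins. Strategy two applies Markov clustering
    (MCL) to an all-versus-all protein-similarity graph spanning vertebrate
    and invertebrate proteomes and filters clusters for conserved
    transmembrane proteins carrying guidance-associated motifs. A
    synthetic-data module generates expression tables, predictor-evidence
    tables and planted-partition similarity graphs with known ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
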