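Package: pertnet
Title: Drug-Perturbation Expression Analysis with Network and Survival Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A seeded, reproducible pipeline linking a drug-perturbation
    expression experiment to downstream systems-level evidence: two-sample
    differential expression with probe collapsing and fold-change filters,
    hypergeometric over-representation and preranked gene set enrichment
    analysis (GSEA), an empirical significance test for module connectivity
    on a protein-protein interaction network (cross-group interaction count
    and largest connected component versus degree-preserving randomized
    networks), cross-cohort concordance bookkeeping, univariate Cox
    proportional-hazards screening with Kaplan-Meier median-split display,
    and transcription-factor regulator nomination. Ships seeded synthetic
    generators for every input class (intensity matrices with planted
    fold-changes, negative-binomial count cohorts, exponential survival
    times with gene-linked hazards, scale-free interaction networks with
    planted modules, and gene-set collections of controllable enrichment)
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
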