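Package: bilayernet
Title: Bilayer Compound-Similarity / Target-Pathway Network Analysis for
    Multi-Component Medicines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and scores the bilayer network used in network
    pharmacology to nominate active constituents of multi-herb
    preparations. Compounds are linked by Tanimoto structural similarity
    into a compound-similarity (CS) network, predicted protein targets are
    linked through shared membership in enriched pathways into a
    target-protein-target (TPT) network, and both layers are partitioned
    into modules by Louvain community detection. Compound-target
    interaction weights are then aggregated into a module-association
    matrix e_uv, and per-compound contributions C(i)_uv rank candidate
    active compounds for a pathway of interest. Includes a planted-structure
    synthetic data generator so the whole pipeline can be exercised and
    validated without proprietary compound or target tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
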