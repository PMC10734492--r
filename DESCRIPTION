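Package: micronet
Title: Paired-Design Gut Microbiome Co-Occurrence Network and Diversity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired two-timepoint gut microbiome studies
    of postpartum weight change. Implements compositional count filtering,
    SparCC correlation inference with permutation p-values, co-occurrence
    network construction with subsample-based group-size equalization,
    alpha diversity (richness, Shannon entropy, Faith's phylogenetic
    diversity) with paired testing, Bray-Curtis dissimilarity with
    PERMANOVA, and per-taxon relative-abundance change testing with
    Benjamini-Hochberg correction. Includes a synthetic-data generator
    emulating a paired cohort design with planted correlation structure,
    diversity shifts, and fold changes, so the full pipeline is testable
    without access to restricted sequence data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    vegan,
    picante,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
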