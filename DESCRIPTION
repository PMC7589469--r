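Package: epilifespan
Title: Lifespan Epistasis Classification for Multi-Gene Mutant Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies lifespan epistasis for multi-gene mutant strains of
    model organisms (C. elegans, D. melanogaster, M. musculus) from cohort
    lifespan records. Implements percent lifespan-change effects relative to
    wild type, the five-way classifier for double mutants (synergistic,
    additive, almost additive, dependent, antagonistic), full and simple
    synergism for n-mutants via bipartition enumeration over gene subsets,
    and partially-known monotonic epistasis along assayed intervention
    paths. Builds the wild-type-to-n-mutant intervention graph, computes
    display effect intervals, exports networks to Cytoscape.js JSON and
    GraphML, and summarises curated database dumps. Ships a synthetic-data
    generator with known ground-truth interaction structure and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
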