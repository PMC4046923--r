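Package: CoilAlign
Title: Coiled-Coil-Aware Pairwise Protein Alignment and Ortholog Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Local protein alignment that models the heptad repeat of
    coiled-coil domains. Proteins are partitioned into coiled-coil and
    non-coiled-coil regions from per-residue predictions; substitution
    matrices are compositionally adjusted per region at fixed relative
    entropy and switched per residue pair inside a Smith-Waterman-Gotoh
    alignment. Register-group matrices (hydrophobic interface a/d,
    intermediate e/g, hydrophilic outside b/c/f), entropy-derived register
    weighting and a register-overlap bonus refine the scoring further.
    Includes reciprocal-best-hit search with method voting, betweenness
    pruning and group merging, a coiled-coil excision benchmark with FDR
    curves, and a seeded generator of synthetic coiled-coil protein
    families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Alignment, SequenceMatching, Proteomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'matrix-base.R'
    'matrix-adjust.R'
    'align.R'
    'search.R'
    'benchmark.R'
    'seq-model.R'
    'io.R'
    'rbh-graph.R'
    'register-matrices.R'
    'stats.R'
    'synth.R'
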