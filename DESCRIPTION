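Package: syntann
Title: Synteny-Aware Annotation of Yeast Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated de novo annotation of budding-yeast genome
    assemblies using a reference database of cross-species homology
    pillars and an ancestral gene order. Protein-coding genes are
    located by translated homology search, assigned to ortholog
    pillars by a neighboring-pillar synteny test that is aware of the
    whole-genome duplication, and turned into gene models by
    classifying the geometry of consecutive high-scoring pairs
    (frameshift, low similarity, intron, duplication). The package
    predicts rare single introns from canonical splice-site,
    branchpoint and 3' acceptor motifs, repairs frameshift sequencing
    errors by voting over primary reads (or patches them with N
    placeholders), checks scaffold integrity against paired reads,
    rescues weak hits in syntenic gaps, sweeps for unannotated large
    ORFs, and propagates retrotransposon flags. A seeded generator of
    ground-truthed synthetic genomes makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
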