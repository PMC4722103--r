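Package: vmine
Title: Targeted Discovery and Assembly of Virophage Genomes from Metagenomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Recruits virophage-like reads from metagenomic sequencing data by
    six-frame translated homology to bait genomes, assembles them with a greedy
    overlap-layout-consensus strategy, extends contigs iteratively against the
    full read set to a fixed point, detects circular genomes via terminal
    direct repeats, and annotates the result (rule-based ORF calling, protein
    homology against a local virophage database, in-silico PCR) before placing
    it on a marker-gene neighbor-joining phylogeny with bootstrap supports. A
    seeded synthetic-metagenome generator emulating a freshwater virophage
    study makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Metagenomics, Assembly, Alignment, Phylogenetics, Sequencing
RoxygenNote: 7.3.3
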