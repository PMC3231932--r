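Package: BacArch
Title: Bacterial Genome Architecture: GC Skew, Replication Origin, Stable-RNA
    Density, Codon Usage Bias and 16S Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the architectural analysis of small circular bacterial
    genomes. Computes windowed GC-content and GC-skew profiles and per-base
    cumulative skew, predicts the replication origin (oriC) and terminus from
    the cumulative-skew extrema with DnaA-gene support, rotates genomes and
    annotations to place oriC at base one, scans IUPAC consensus motifs
    (DnaA boxes, TTATNCACA), groups rRNA genes into 16S-23S-5S operons and
    ranks genomes by rRNA operon density under free-living/Candidatus survey
    rules, scores per-gene codon usage bias with a reference-set adaptation
    index and RSCU, assembles genome feature statistics tables, and builds
    neighbor-joining 16S trees with bootstrap supports from p-distance
    matrices with pairwise deletion. A seeded synthetic-genome and alignment
    simulator with full ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Sequencing, Phylogenetics, Software
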