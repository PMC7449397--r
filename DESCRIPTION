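Package: ccspace
Title: Coiled Coil Sequence Space Analysis for L1 Retrotransposon Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the protein sequence space of repeat-family
    coding sequences, built around the N-terminal coiled coil of the LINE-1
    (L1) ORF1 protein. Provides CpG-decay-aware ("CG-null") translation of
    codon alignments, CG-restored nucleotide consensus reconstruction,
    threshold protein consensus building, one-hot principal component
    analysis with cross-family projection, per-family metric
    multidimensional scaling with K-means cluster retrieval and
    supplementary-point projection, greedy identity sub-clustering,
    mosaic-variant difference accounting with heptad register annotation,
    distance-based tree construction over cluster consensuses, and a
    forward simulator of L1-family succession with post-insertion CpG
    hypermutation that supplies ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    cluster,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
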