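Package: panarch
Title: Pangenome Analysis from Protein Domain Architectures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes bacterial pangenomes from domain sequence families,
    i.e. proteins clustered by their ordered, non-overlapping Pfam domain
    architecture. Provides merging and comparison of gene predictions from
    several gene finders, translation of open reading frames, parsing and
    E-value filtering of HMMER3 domtblout scan results, recursive
    elimination of overlapping domain hits, construction of the genomes by
    families pan-matrix with its frequency spectrum, diversity measures
    (Jaccard distance, genome fluidity, Manhattan distances, PCA, pangenome
    trees), estimation of population pangenome and core size by a
    zero-truncated binomial mixture model fitted with EM and selected by
    BIC, expected genome overlap, bagging-based uncertainty intervals, and
    permutation-based Heaps law analysis of pangenome openness. A synthetic
    data generator emulates every input format so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
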