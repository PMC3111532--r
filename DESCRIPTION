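Package: orthoconj
Title: Testing the Ortholog Conjecture with Functional and Expression Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify functional similarity between orthologs and
    paralog subtypes as a function of protein sequence divergence. Implements
    Gene Ontology term propagation and the Maryland bridge set-overlap
    statistic, gene-tree based classification of homologous pairs into
    one-to-one orthologs, inparalogs and within/between-species outparalogs,
    Needleman-Wunsch percent identity and Nei-Gojobori dN/dS, two-step z-score
    normalization of cross-tissue microarray expression with probe-to-gene
    mapping, binned similarity-versus-divergence curves with rank-based tests,
    a per-family best-ortholog versus best-paralog resampling analysis, a set
    of annotation-bias control filters, and a seeded synthetic-data generator
    that emulates the statistical structure of two-species comparative
    functional genomic data for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
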