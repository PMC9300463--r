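Package: baitminer
Title: Bait-Anchored Co-Expression Mining for Biosynthetic Pathway Gene
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the tissue-filtered,
    bait-anchored co-expression strategy used to discover plant specialized
    metabolism genes (e.g. the strychnine, brucine and diaboline pathway in
    Strychnos): FPKM quantification and root-expression filtering of
    replicated multi-tissue transcriptomes, Pearson co-expression sets
    anchored on one or several bait genes, family-stratified candidate
    tables, global protein alignment with percent identity and
    reciprocal-best-hit orthologue mapping between producer and non-producer
    proteomes, neighbor-joining clade assignment, and Michaelis-Menten
    steady-state enzyme kinetics.  A negative-binomial synthetic-data
    generator plants a known root-preferential pathway module so that every
    stage of the discovery pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
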