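Package: litmine
Title: Literature Mining of PubMed Abstracts for Drug Repositioning via
    KEGG Concept Distance Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Links biomedical concepts identified by KEGG codes through
    their co-occurrence in PubMed abstracts.  Search terms are derived
    from KEGG NAME/DEFINITION fields, normalised with a
    biomedical-specificity-preserving variant of the Snowball English
    stemmer, and matched against abstracts through an inverted index.
    Pairwise association is scored by conditional probability, the Dice
    index or the Otsuka-Ochiai (cosine) coefficient; distances defined as
    the negative log of the maximal coefficient are concatenated through a
    shortest-path tree rooted at a disease code, so that drugs with no
    co-published literature still receive a finite, rankable indirect
    distance.  Includes a synthetic corpus generator with planted
    co-occurrence structure for end-to-end validation without database
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    ape,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
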