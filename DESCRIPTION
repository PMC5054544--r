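Package: cidre
Title: Chemical-Induced Disease Relation Extraction from Biomedical Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A document-level relation extraction system for chemical-induced
    disease (CID) assertions in PubMed-style title/abstract documents. Reads
    PubTator-format corpora with entity mentions normalized to MeSH concept
    identifiers, builds per-sentence Extended Dependency Graphs (syntactic
    dependencies augmented with numbered-argument and semantic edges plus
    argument propagation), extracts bag-of-words, bag-of-ngram, trigger-pattern,
    shortest-path walk, and statistical features for every candidate
    <chemical, disease> concept pair, and classifies pairs with a linear
    support vector machine. Includes distant supervision utilities that turn
    curated document-level relation tables into weakly labeled training
    corpora, micro-averaged precision/recall/F1 evaluation, and a
    deterministic synthetic corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
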