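Package: goclassify
Title: Gene Ontology Term Assignment from Free Text by k-NN and
    Thesaurus Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns Gene Ontology (GO) terms to biomedical free text
    (abstracts or article sections) with two complementary classifiers
    and their linear combination. A k-nearest-neighbour classifier
    retrieves the most similar already-curated abstracts from a
    knowledge base built from GOA annotation files (GAF) and aggregates
    their curated GO terms into a ranked functional profile; a
    thesaurus-based classifier ranks GO terms by lexical similarity
    between term names/synonyms and the text, boosted by fuzzy pattern
    matches.  Includes an OBO 1.2 ontology reader, an Okapi BM25
    retrieval engine with Porter stemming, temporal knowledge-base
    filtering for year-by-year simulation, mean-reciprocal-rank and
    recall-at-k evaluation compatible with TREC run/qrels formats, and
    a synthetic corpus generator with known term-vocabulary structure
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
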