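Package: qualrank
Title: Quality-Centred Multidimensional Ranking for Health Web Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality-centred retrieval of online health information.
    Implements a two-phase ranking pipeline -- BM25 preprocessing over a dual
    (default and known-item-tuned) index, followed by parallel reranking along
    the usefulness, supportiveness, and credibility quality dimensions with
    reciprocal rank fusion -- together with the help/harm compatibility
    evaluation metric based on truncated, normalized rank-biased overlap.
    Includes readers and writers for TREC-style topics, runs, and
    multidimensional relevance judgments; a stance-tiered reranker driven by
    pluggable claim-checking models; web-credibility features (SMOG
    readability, CSS design effort, page rank) with a random-forest
    classifier harness; and a synthetic benchmark generator with
    fidelity-controlled mock scorers so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    randomForest,
    stats,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
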