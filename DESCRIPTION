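Package: gerolit
Title: Literature Mining of Human Aging and Longevity into Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A text-mining pipeline that turns biomedical abstracts into a
    typed entity-relation knowledge graph with aging and longevity biomarker
    calls. Implements dictionary-based named entity recognition over
    HGNC/MeSH/dbSNP-style lexicons with rule-based miRNA/lncRNA recognition,
    dependency-path relation extraction with main-verb voice resolution and
    negation filtering, polarity-based biomarker classification, export to
    graph-database CSV and structured JSON, set-overlap evaluation against
    reference gene lists, and a deterministic synthetic-corpus generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
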