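Package: sempar
Title: Semantic Particularity and Similarity of Ontology-Annotated Gene Sets
Version: 0.1.0
Authors@R: person("sempar", "maintainers", email = "sempar@example.org",
    role = c("aut", "cre"))
Description: Compares Gene Ontology (or any DAG-structured ontology)
    annotation sets of genes by a tuple of one symmetric semantic
    similarity and two directional semantic particularity values.
    Particularity quantifies the informativeness carried by the terms of
    one set that are not related to any term of the other set, normalised
    to [0,1]. Term informativeness can be backed by Wang's semantic value
    (corpus-independent, suited to cross-species comparison), by
    information content derived from an annotation corpus, or by an
    explicit table. Includes an OBO reader, a GAF/TSV annotation reader
    with true-path-rule propagation, Wang and Lin set similarities,
    batch machinery for pairwise matrices, similarity-binned
    particularity statistics and similarity/particularity profile
    classification, plus seeded synthetic ontology and corpus generators
    so the whole stack is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
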