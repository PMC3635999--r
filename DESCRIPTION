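Package: ontenrich
Title: Multi-Ontology Term Enrichment from Text-Derived Gene Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates genes and proteins to terms from multiple OBO
    ontologies by exact dictionary matching of term names and synonyms
    against curated descriptive text (gene summaries, GeneRIFs,
    publication titles, keywords), propagates annotations to ancestor
    terms along is_a relations, and tests study gene sets against a
    background for per-ontology term enrichment or depletion with the
    hypergeometric test and Bonferroni, Holm or Benjamini-Hochberg
    correction.  Includes same-name result merging across ontologies,
    category and keyword filters, precision/recall evaluation of
    automatic annotations against gold-standard tables, a deterministic
    synthetic-fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
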