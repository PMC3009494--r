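Package: godelppi
Title: Prime-Number Encoding of Ontology DAGs and Semantic Search over
    Protein-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes an ontology (e.g. the Gene Ontology) by assigning a
    distinct prime number to every term and representing each term by the
    squarefree product of the primes of the term and all of its ancestors
    (a modified Goedel number). Subsumption between terms, and between query
    terms and annotated proteins, then reduces to exact integer divisibility
    on arbitrary-precision integers. On top of the encoding the package
    provides an ontology-aware search engine for protein-protein interaction
    corpora (find proteins by term, partner search with conditions,
    conjunctive multi-term queries, term autocomplete), inference of
    protein-protein interactions from domain-domain interactions by the same
    arithmetic, an OBO flat-file parser, PSI-MI 2.5 XML export, and seeded
    synthetic-fixture generators for ontologies and interaction corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    openssl,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
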