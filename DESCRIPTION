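Package: comodiff
Title: Semantic Differencing of Computational Biology Model Versions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the difference (delta) between two versions of an
    XML-encoded computational biology model (SBML or CellML) as a set of
    insertion, deletion, update and move operations, applies deltas as
    patches, and annotates every change with terms from the COMODI change
    ontology (change type, XML entity, affected model layer). Causally
    dependent changes are linked (wasTriggeredBy), annotations are
    serialized as RDF/Turtle independently of the diff file, and change
    sets can be filtered by ontology term with subsumption, including
    collapsing of version series to the versions that carry relevant
    changes. A fixtures generator produces seeded SBML/CellML version
    pairs with known expected annotations, and a command-line interface
    exposes the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
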