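test_that("built-in vocabulary has the documented structure", {
  voc <- comodi_vocabulary()
  expect_setequal(voc$properties$name,
                  c("affects", "appliesTo", "hasIntention", "hasReason",
                    "wasTriggeredBy"))
  expect_true(all(voc$properties$domain == "Change"))
  ranges <- setNames(voc$properties$range, voc$properties$name)
  expect_identical(ranges[["affects"]], "Target")
  expect_identical(ranges[["appliesTo"]], "XmlEntity")
  expect_identical(ranges[["hasIntention"]], "Intention")
  expect_identical(ranges[["hasReason"]], "Reason")
  expect_identical(ranges[["wasTriggeredBy"]], "Change")

  roots <- voc$terms$id[is.na(voc$terms$parent)]
  expect_setequal(roots, c("Change", "XmlEntity", "Intention", "Reason", "Target"))
  children <- function(p) voc$terms$id[!is.na(voc$terms$parent) & voc$terms$parent == p]
  expect_setequal(children("Change"), c("Insertion", "Deletion", "Update", "Move"))
  expect_setequal(children("XmlEntity"), c("XmlNode", "XmlAttribute", "XmlText"))
  expect_setequal(children("Target"),
                  c("ModelEncoding", "ModelAnnotation", "ModelDefinition",
                    "ModelSetup", "ModelBehaviour"))
  # idempotence
  expect_identical(comodi_vocabulary(), comodi_vocabulary())
  expect_identical(load_builtin_vocabulary(), voc)
})

test_that("is_a walks the parent chain reflexively", {
  voc <- comodi_vocabulary()
  expect_true(is_a(voc, "ParameterSetup", "ModelSetup"))
  expect_true(is_a(voc, "ParameterSetup", "ParameterSetup"))
  expect_true(is_a(voc, "KineticsDefinition", "Target"))
  expect_false(is_a(voc, "Insertion", "Target"))
  expect_false(is_a(voc, "ModelSetup", "ParameterSetup"))
  expect_error(is_a(voc, "NotATerm", "Target"), "unknown term 'NotATerm'")
  expect_error(is_a(voc, "Update", "Nope"), "unknown term 'Nope'")
})

test_that("subsumption is a partial order and every term reaches one root", {
  voc <- comodi_vocabulary()
  ids <- voc$terms$id
  roots <- ids[is.na(voc$terms$parent)]
  # independent oracle: brute-force parent-chain walk on the term table
  chain <- function(id) {
    out <- id
    while (!is.na(voc$terms$parent[voc$terms$id == id])) {
      id <- voc$terms$parent[voc$terms$id == id]
      out <- c(out, id)
    }
    out
  }
  for (x in ids) {
    expect_true(is_a(voc, x, x))
    expect_identical(sum(chain(x) %in% roots), 1L)
    for (y in ids) {
      expect_identical(is_a(voc, x, y), y %in% chain(x))
      if (x != y && is_a(voc, x, y)) expect_false(is_a(voc, y, x))
      if (is_a(voc, x, y)) {
        for (z in chain(y)) expect_true(is_a(voc, x, z))
      }
    }
  }
})

test_that("turtle export round-trips and counts one subclass triple per non-root term", {
  voc <- comodi_vocabulary()
  ttl <- vocabulary_to_turtle(voc)
  n_nonroot <- sum(!is.na(voc$terms$parent))
  expect_identical(
    lengths(regmatches(ttl, gregexpr("rdfs:subClassOf", ttl)))[[1]],
    n_nonroot)
  voc2 <- vocabulary_from_turtle(ttl)
  expect_identical(voc2$terms, voc$terms)
  expect_identical(voc2$properties, voc$properties)
  expect_identical(voc2$version, voc$version)
  expect_identical(voc2$base_iri, voc$base_iri)
})

test_that("empty vocabulary exports prefixes and header only", {
  voc <- comodi_vocabulary()
  voc$terms <- voc$terms[0, ]
  voc$properties <- voc$properties[0, ]
  ttl <- vocabulary_to_turtle(voc)
  body <- Filter(nzchar, strsplit(ttl, "\n")[[1]])
  expect_true(all(grepl("^(@prefix|<|    owl:versionInfo)", body)))
  expect_false(grepl("owl:Class", ttl, fixed = TRUE))
})

test_that("exported turtle is valid per an independent RDF parser", {
  ttl <- vocabulary_to_turtle(comodi_vocabulary())
  tf <- tempfile(fileext = ".ttl")
  writeLines(ttl, tf)
  ours <- nrow(comodiff:::parse_turtle(ttl)$triples)
  theirs <- system2("python",
                    c("-c",
                      shQuote("import sys, rdflib; g = rdflib.Graph(); g.parse(sys.argv[1], format='turtle'); print(len(g))"),
                      tf),
                    stdout = TRUE, stderr = FALSE)
  expect_identical(as.integer(theirs[length(theirs)]), ours)
})

test_that("OWL loader reads a synthetic RDF/XML vocabulary", {
  owl <- paste0(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
              xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
              xmlns:owl="http://www.w3.org/2002/07/owl#">
       <owl:Ontology rdf:about="http://purl.uni-rostock.de/comodi/comodi">
         <owl:versionInfo>synthetic-test</owl:versionInfo>
       </owl:Ontology>
       <owl:Class rdf:about="http://purl.uni-rostock.de/comodi/comodi#Change">
         <rdfs:label>Change</rdfs:label>
       </owl:Class>
       <owl:Class rdf:about="http://purl.uni-rostock.de/comodi/comodi#Update">
         <rdfs:subClassOf rdf:resource="http://purl.uni-rostock.de/comodi/comodi#Change"/>
       </owl:Class>
       <owl:ObjectProperty rdf:about="http://purl.uni-rostock.de/comodi/comodi#affects">
         <rdfs:domain rdf:resource="http://purl.uni-rostock.de/comodi/comodi#Change"/>
         <rdfs:range rdf:resource="http://purl.uni-rostock.de/comodi/comodi#Change"/>
       </owl:ObjectProperty>
     </rdf:RDF>')
  tf <- tempfile(fileext = ".owl")
  writeLines(owl, tf)
  voc <- read_owl_vocabulary(tf)
  expect_setequal(voc$terms$id, c("Change", "Update"))
  expect_identical(voc$terms$parent[voc$terms$id == "Update"], "Change")
  expect_identical(voc$properties$name, "affects")
  expect_identical(voc$version, "synthetic-test")
  expect_true(is_a(voc, "Update", "Change"))
})
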