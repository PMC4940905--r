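test_that("identical documents match node for node and yield an empty delta", {
  doc <- make_base_model("sbml", 3, 2, seed = 1)
  copy <- model_from_xml(model_to_xml(doc))
  m <- match_trees(doc, copy)
  n_nodes <- length(comodiff:::tree_nodes(doc$tree))
  expect_identical(nrow(m$pairs), n_nodes)
  expect_length(compute_delta(doc, copy, m)$operations, 0L)
})

test_that("parameter nodes are matched by id despite differing values", {
  p <- km1_pair()
  m <- match_trees(p$a, p$b)
  d <- compute_delta(p$a, p$b, m)
  expect_length(d$operations, 1L)
  op <- d$operations[[1]]
  expect_identical(op$kind, "Update")
  expect_identical(op$entity_kind, "XmlAttribute")
  expect_identical(op$attribute, "value")
  expect_identical(op$old_value, "23.24")
  expect_identical(op$new_value, "23.42")
})

test_that("documents with disjoint ids and tags share no matches", {
  a <- model_from_xml('<foo><x id="a1"/><y name="n1"/></foo>')
  b <- model_from_xml('<bar><p id="b1"/><q name="n2"/></bar>')
  m <- match_trees(a, b, dialect = "generic")
  expect_identical(nrow(m$pairs), 0L)
  # same root tag: only the roots match
  b2 <- model_from_xml('<foo><p id="b1"/></foo>')
  m2 <- match_trees(a, b2, dialect = "generic")
  expect_identical(nrow(m2$pairs), 1L)
})

test_that("node insertion emits per-attribute operations triggered by the node", {
  base <- make_base_model("sbml", 3, 1, seed = 1)
  mut <- apply_mutation(base, "species_insert", seed = 1)
  d <- compute_delta(base, mut$doc)
  node_ins <- Filter(function(o) o$entity_kind == "XmlNode", d$operations)
  attr_ins <- Filter(function(o) o$entity_kind == "XmlAttribute", d$operations)
  expect_length(node_ins, 1L)
  expect_identical(node_ins[[1]]$kind, "Insertion")
  expect_length(attr_ins, 5L)  # id, metaid, name, compartment, initialConcentration
  for (op in attr_ins) {
    expect_identical(op$kind, "Insertion")
    expect_identical(op$triggered_by, node_ins[[1]]$op_id)
  }
  expect_identical(canonicalize(apply_delta(base, d)), canonicalize(mut$doc))
})

test_that("patch round-trips every generated fixture pair", {
  for (fx in fixture_pairs(seeds = 1:2)) {
    d <- compute_delta(fx$base, fx$mutated)
    patched <- apply_delta(fx$base, d)
    expect_identical(canonicalize(patched), canonicalize(fx$mutated),
                     label = sprintf("%s seed %d", fx$mutation, fx$seed))
  }
})

test_that("forward and reverse deltas have equal size with kinds swapped", {
  swap <- c(Insertion = "Deletion", Deletion = "Insertion",
            Update = "Update", Move = "Move")
  for (m in setdiff(mutation_types(), "reshuffle_parameters")) {
    base <- make_base_model("sbml", 4, 2, seed = 2)
    mut <- apply_mutation(base, m, seed = 2)
    fwd <- table(vapply(compute_delta(base, mut$doc)$operations,
                        function(o) o$kind, character(1)))
    rev <- table(vapply(compute_delta(mut$doc, base)$operations,
                        function(o) o$kind, character(1)))
    for (k in names(fwd)) {
      expect_identical(unname(rev[swap[[k]]]), unname(fwd[[k]]),
                       label = sprintf("%s: %s", m, k))
    }
  }
})

test_that("patching with an empty delta is the identity", {
  doc <- make_base_model("sbml", 2, 1, seed = 1)
  d <- compute_delta(doc, doc)
  expect_identical(canonicalize(apply_delta(doc, d)), canonicalize(doc))
})

test_that("unresolvable addresses and write conflicts are reported by op id", {
  p <- km1_pair()
  d <- compute_delta(p$a, p$b)
  d$operations[[1]]$address_a <- "/sbml[1]/model[1]/listOfParameters[1]/parameter[9]"
  expect_error(apply_delta(p$a, d), "unresolvable address.*op1")
  d2 <- compute_delta(p$a, p$b)
  dup <- d2$operations[[1]]
  dup$op_id <- "op2"
  dup$new_value <- "99"
  d2$operations <- c(d2$operations, list(dup))
  expect_error(apply_delta(p$a, d2), "conflict")
})

test_that("delta serialization round-trips and is byte-deterministic", {
  for (fx in fixture_pairs(seeds = 1)) {
    d <- compute_delta(fx$base, fx$mutated)
    xml1 <- write_delta(d)
    xml2 <- write_delta(compute_delta(fx$base, fx$mutated))
    expect_identical(xml1, xml2, label = fx$mutation)
    d2 <- read_delta(xml1)
    expect_identical(write_delta(d2), xml1, label = fx$mutation)
    expect_identical(canonicalize(apply_delta(fx$base, d2)),
                     canonicalize(fx$mutated), label = fx$mutation)
  }
})

test_that("the Km1 diff XML carries both old and new values", {
  p <- km1_pair()
  xml <- write_delta(compute_delta(p$a, p$b))
  doc <- xml2::read_xml(xml)
  ops <- xml2::xml_find_all(doc, "./*")
  expect_length(ops, 1L)
  expect_identical(xml2::xml_attr(ops[[1]], "oldValue"), "23.24")
  expect_identical(xml2::xml_attr(ops[[1]], "newValue"), "23.42")
  # empty delta serializes with zero operation elements
  empty <- write_delta(compute_delta(p$a, p$a))
  expect_length(xml2::xml_find_all(xml2::read_xml(empty), "./*"), 0L)
})

test_that("schema violations in diff XML are listed per operation", {
  bad <- paste0('<modelDiff xmlns="', comodiff:::DIFF_NS, '" dialect="sbml">',
                '<operation id="op1" kind="Update" entity="XmlAttribute"',
                ' addressA="/a[1]" attribute="x" oldValue="1" newValue="1"/>',
                '<operation id="op2" kind="Insertion" entity="XmlNode"',
                ' addressA="/a[1]" addressB="/a[1]/b[1]"/>',
                '</modelDiff>')
  expect_error(read_delta(bad), "op1.*oldValue != newValue")
  expect_error(read_delta(bad), "op2.*must not carry addressA")
})

test_that("moves across parents are detected and patch correctly", {
  a <- model_from_xml('<sbml xmlns="http://www.sbml.org/sbml/level2/version4">
    <model id="m"><listOfA><parameter id="p1" value="1"/></listOfA><listOfB/></model></sbml>')
  b <- model_from_xml('<sbml xmlns="http://www.sbml.org/sbml/level2/version4">
    <model id="m"><listOfA/><listOfB><parameter id="p1" value="1"/></listOfB></model></sbml>')
  d <- compute_delta(a, b)
  kinds <- vapply(d$operations, function(o) o$kind, character(1))
  expect_identical(unique(kinds), "Move")
  expect_identical(canonicalize(apply_delta(a, d)), canonicalize(b))
})
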