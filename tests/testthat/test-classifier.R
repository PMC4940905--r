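test_that("XML entity classification follows the operation's address", {
  p <- km1_pair()
  d <- compute_delta(p$a, p$b)
  expect_identical(classify_entity(d$operations[[1]]), "XmlAttribute")

  base <- make_base_model("sbml", 3, 1, seed = 1)
  del <- apply_mutation(base, "species_delete", seed = 1)
  dd <- compute_delta(base, del$doc)
  node_del <- Filter(function(o) o$entity_kind == "XmlNode", dd$operations)[[1]]
  expect_identical(classify_entity(node_del), "XmlNode")

  a <- model_from_xml("<m><notes>old text</notes></m>")
  b <- model_from_xml("<m><notes>new text</notes></m>")
  dt <- compute_delta(a, b, dialect = "generic")
  expect_identical(classify_entity(dt$operations[[1]]), "XmlText")
})

test_that("target classification applies the SBML rule table", {
  p <- km1_pair()
  d <- compute_delta(p$a, p$b)
  expect_identical(classify_target(d$operations[[1]], "sbml"), "ParameterSetup")

  base <- make_base_model("sbml", 3, 1, seed = 1)
  up <- apply_mutation(base, "spec_upgrade", seed = 1)
  du <- compute_delta(base, up$doc)
  for (op in du$operations) {
    expect_identical(classify_target(op, "sbml"), "ModelEncoding")
  }

  ren <- apply_mutation(base, "typo_rename", seed = 1)
  dr <- compute_delta(base, ren$doc)
  targets <- classify_target(dr$operations[[1]], "sbml")
  expect_true("EntityName" %in% targets)
  expect_true("ReactionNetworkDefinition" %in% targets)

  # nearest enclosing construct: math inside a kinetic law is kinetics
  a <- model_from_xml(sprintf('<sbml xmlns="%s"><model id="m"><listOfReactions>
    <reaction id="R1"><kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">
    <ci>x</ci></math></kineticLaw></reaction>
    </listOfReactions></model></sbml>', SBML_L2))
  b <- model_from_xml(gsub("<ci>x</ci>", "<ci>y</ci>", model_to_xml(a), fixed = TRUE))
  dk <- compute_delta(a, b)
  expect_identical(classify_target(dk$operations[[1]], "sbml"), "KineticsDefinition")
})

test_that("cellml initial_value changes affect the parameter setup", {
  cb <- make_base_model("cellml", 3, 2, seed = 1)
  mut <- apply_mutation(cb, "parameter_value_update", seed = 1)
  d <- compute_delta(cb, mut$doc)
  expect_length(d$operations, 1L)
  targets <- classify_target(d$operations[[1]], "cellml")
  expect_true("ParameterSetup" %in% targets)
})

test_that("deleting a reaction triggers the deletion of its kinetic law", {
  base <- make_base_model("sbml", 4, 2, seed = 1)
  mut <- apply_mutation(base, "reaction_delete", seed = 1)
  d <- compute_delta(base, mut$doc)
  ops <- d$operations
  node_del <- function(tag) {
    Filter(function(o) o$kind == "Deletion" && o$entity_kind == "XmlNode" &&
             grepl(sprintf("%s\\[[0-9]+\\]$", tag), o$address_a), ops)
  }
  rx <- node_del("reaction")
  kl <- node_del("kineticLaw")
  expect_length(rx, 1L)
  expect_length(kl, 1L)
  expect_true(rx[[1]]$op_id %in% kl[[1]]$triggered_by)
})

test_that("deleting a node triggers all of its attribute deletions", {
  base <- make_base_model("sbml", 4, 2, seed = 1)
  mut <- apply_mutation(base, "species_delete", seed = 1)
  d <- compute_delta(base, mut$doc)
  node_ops <- Filter(function(o) o$entity_kind == "XmlNode", d$operations)
  attr_ops <- Filter(function(o) o$entity_kind == "XmlAttribute", d$operations)
  expect_length(node_ops, 1L)
  expect_length(attr_ops, 5L)
  # oracle: address containment decides the trigger
  for (op in attr_ops) {
    expect_identical(op$address_a, node_ops[[1]]$address_a)
    expect_identical(op$triggered_by, node_ops[[1]]$op_id)
  }
  # trigger inference is idempotent and acyclic
  d2 <- infer_triggers(d)
  expect_identical(write_delta(d2), write_delta(d))
})

test_that("a single update carries no trigger links", {
  p <- km1_pair()
  d <- compute_delta(p$a, p$b)
  expect_length(d$operations[[1]]$triggered_by, 0L)
})

test_that("annotate_delta combines automatic and user-supplied branches", {
  p <- km1_pair()
  d <- compute_delta(p$a, p$b)
  anns <- annotate_delta(d, user_annotations = list(
    op1 = list(has_intention = "Correction",
               has_reason = "MismatchWithPublication")))
  expect_length(anns, 1L)
  a <- anns[[1]]
  expect_identical(a$change_term, "Update")
  expect_identical(a$applies_to, "XmlAttribute")
  expect_identical(a$affects, "ParameterSetup")
  expect_identical(a$has_intention, "Correction")
  expect_identical(a$has_reason, "MismatchWithPublication")

  # empty delta annotates to an empty set
  expect_length(annotate_delta(compute_delta(p$a, p$a)), 0L)
})

test_that("user terms violating a property range are rejected", {
  p <- km1_pair()
  d <- compute_delta(p$a, p$b)
  expect_error(
    annotate_delta(d, user_annotations = list(op1 = list(has_intention = "ParameterSetup"))),
    "range violation.*hasIntention.*Intention.*ParameterSetup")
  expect_error(
    annotate_delta(d, user_annotations = list(op1 = list(has_reason = "XmlNode"))),
    "range violation.*hasReason")
  expect_error(
    annotate_delta(d, user_annotations = list(op9 = list(has_reason = "Typo"))),
    "unknown operation id 'op9'")
})

test_that("every fixture annotation validates against the property ranges", {
  voc <- comodi_vocabulary()
  for (fx in fixture_pairs(seeds = 1)) {
    anns <- annotate_delta(compute_delta(fx$base, fx$mutated))
    for (a in anns) {
      expect_true(is_a(voc, a$change_term, "Change"))
      expect_true(is_a(voc, a$applies_to, "XmlEntity"))
      for (t in a$affects) expect_true(is_a(voc, t, "Target"))
    }
    # repeated runs are identical (classification is pure)
    anns2 <- annotate_delta(compute_delta(fx$base, fx$mutated))
    expect_identical(anns, anns2, label = fx$mutation)
  }
})
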