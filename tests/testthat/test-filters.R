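test_that("order-only detection requires a same-parent move in an unordered container", {
  base <- make_base_model("sbml", 3, 2, seed = 1)
  mut <- apply_mutation(base, "reshuffle_parameters", seed = 1)
  d <- compute_delta(base, mut$doc)
  moves <- Filter(function(o) o$kind == "Move", d$operations)
  expect_gt(length(moves), 0L)
  for (op in moves) expect_true(is_order_only(op, "sbml"))

  p <- km1_pair()
  upd <- compute_delta(p$a, p$b)$operations[[1]]
  expect_false(is_order_only(upd, "sbml"))

  # cross-parent move is not order-only (oracle: parent address comparison)
  a <- model_from_xml('<m><u><x id="i1"/></u><v/></m>')
  b <- model_from_xml('<m><u/><v><x id="i1"/></v></m>')
  mv <- compute_delta(a, b, dialect = "generic")$operations[[1]]
  expect_identical(mv$kind, "Move")
  expect_false(identical(comodiff:::address_parent(mv$address_a),
                         comodiff:::address_parent(mv$address_b)))
  expect_false(is_order_only(mv, "sbml", unordered = "u"))
})

mixed_fixture <- function(seed = 1) {
  base <- make_base_model("sbml", 4, 2, seed = seed)
  s1 <- apply_mutation(base, "spec_upgrade", seed = seed)
  s2 <- apply_mutation(s1$doc, "parameter_value_update", seed = seed)
  s3 <- apply_mutation(s2$doc, "reshuffle_parameters", seed = seed)
  d <- compute_delta(base, s3$doc)
  anns <- annotate_delta(d)
  enc_ids <- vapply(Filter(function(a) "ModelEncoding" %in% a$affects, anns),
                    function(a) a$op_id, character(1))
  user <- setNames(
    rep(list(list(has_reason = "ChangedSpecification")), length(enc_ids)),
    enc_ids)
  list(delta = d, anns = annotate_delta(d, user_annotations = user),
       enc_ids = enc_ids)
}

test_that("filtering by ChangedSpecification isolates the spec-upgrade changes", {
  fx <- mixed_fixture()
  kept <- filter_changes(fx$anns, filter_profile(include = "ChangedSpecification"))
  expect_setequal(vapply(kept, function(a) a$op_id, character(1)), fx$enc_ids)
})

test_that("dropping order-only changes removes the reshuffle moves", {
  fx <- mixed_fixture()
  kept <- filter_changes(fx$anns, filter_profile(drop_order_only = TRUE))
  expect_false(any(vapply(kept, function(a) a$order_only, logical(1))))
  expect_lt(length(kept), length(fx$anns))
  dropped <- setdiff(vapply(fx$anns, function(a) a$op_id, character(1)),
                     vapply(kept, function(a) a$op_id, character(1)))
  for (id in dropped) {
    a <- fx$anns[[which(vapply(fx$anns, function(x) x$op_id == id, logical(1)))]]
    expect_identical(a$change_term, "Move")
  }
})

test_that("subsumption keeps ParameterSetup changes under include ModelSetup", {
  fx <- mixed_fixture()
  kept <- filter_changes(fx$anns, filter_profile(include = "ModelSetup"))
  expect_true(all(vapply(kept, function(a) "ParameterSetup" %in% a$affects,
                         logical(1))))
  expect_gt(length(kept), 0L)
  # without subsumption the abstract term matches nothing
  none <- filter_changes(fx$anns, filter_profile(include = "ModelSetup",
                                                 use_subsumption = FALSE))
  expect_length(none, 0L)
})

test_that("empty profiles are a no-op and filtering is idempotent and monotone", {
  fx <- mixed_fixture()
  anns <- fx$anns
  expect_identical(filter_changes(anns, filter_profile()), anns)
  prof <- filter_profile(include = "ModelSetup", drop_order_only = TRUE)
  once <- filter_changes(anns, prof)
  twice <- filter_changes(once, prof)
  expect_identical(twice, once)
  expect_true(all(vapply(once, function(a) a$op_id, character(1)) %in%
                    vapply(anns, function(a) a$op_id, character(1))))
  # enlarging include never shrinks the result
  bigger <- filter_changes(anns, filter_profile(include = c("ModelSetup", "ModelEncoding"),
                                                drop_order_only = TRUE))
  expect_true(all(vapply(once, function(a) a$op_id, character(1)) %in%
                    vapply(bigger, function(a) a$op_id, character(1))))
  # enlarging exclude never grows it
  ex1 <- filter_changes(anns, filter_profile(exclude = "ModelEncoding"))
  ex2 <- filter_changes(anns, filter_profile(exclude = c("ModelEncoding", "ModelSetup")))
  expect_true(all(vapply(ex2, function(a) a$op_id, character(1)) %in%
                    vapply(ex1, function(a) a$op_id, character(1))))
  # include = Target keeps exactly the changes with any affects term
  tgt <- filter_changes(anns, filter_profile(include = "Target"))
  expect_setequal(vapply(tgt, function(a) a$op_id, character(1)),
                  vapply(Filter(function(a) length(a$affects) > 0, anns),
                         function(a) a$op_id, character(1)))
  expect_error(filter_changes(anns, filter_profile(include = "NoTerm")),
               "unknown term 'NoTerm'")
  expect_error(filter_profile(include = "X", exclude = "X"), "overlap")
})

test_that("version series collapse to the versions with relevant changes", {
  base <- make_base_model("sbml", 4, 2, seed = 1)
  v1 <- apply_mutation(base, "spec_upgrade", seed = 1)       # encoding only
  v2 <- apply_mutation(v1$doc, "reshuffle_parameters", seed = 1)  # order only
  v3 <- apply_mutation(v2$doc, "parameter_value_update", seed = 1)
  series <- list(
    annotate_delta(compute_delta(base, v1$doc)),
    annotate_delta(compute_delta(v1$doc, v2$doc)),
    annotate_delta(compute_delta(v2$doc, v3$doc)))
  prof <- filter_profile(exclude = "ModelEncoding", drop_order_only = TRUE)
  expect_identical(collapse_versions(series, prof), 3L)
  # empty profile keeps every version with a non-empty delta
  expect_identical(collapse_versions(series, filter_profile()), c(1L, 2L, 3L))
  # all-empty series collapses to nothing
  empty <- annotate_delta(compute_delta(base, base))
  expect_identical(collapse_versions(list(empty, empty), filter_profile()),
                   integer())
})

test_that("named audience profiles behave as documented", {
  fx <- mixed_fixture()
  mod <- filter_changes(fx$anns, builtin_profile("modeller"))
  expect_true(all(vapply(mod, function(a) {
    any(c("ParameterSetup", "ModelSetup", "ModelDefinition") %in% a$affects) ||
      any(vapply(a$affects, function(t) is_a(comodi_vocabulary(), t, "ModelDefinition"),
                 logical(1)))
  }, logical(1))))
  cur <- filter_changes(fx$anns, builtin_profile("curator"))
  expect_false(any(vapply(cur, function(a) a$order_only, logical(1))))
  expect_gte(length(cur), length(mod))
})
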