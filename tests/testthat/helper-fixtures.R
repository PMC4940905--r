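# Shared fixture builders. Everything is generated in code; no binary or
# stored fixtures.

SBML_L2 <- "http://www.sbml.org/sbml/level2/version4"

minimal_sbml <- function(km1_value) {
  model_from_xml(sprintf(
    '<sbml xmlns="%s" level="2" version="4"><model id="m">
       <listOfParameters>
         <parameter id="Km1" value="%s" units="molesperlitre"/>
       </listOfParameters>
     </model></sbml>', SBML_L2, km1_value))
}

km1_pair <- function() {
  list(a = minimal_sbml("23.24"), b = minimal_sbml("23.42"))
}

# one generated version pair per (mutation, seed), with ground truth
fixture_pairs <- function(seeds = 1:2, dialect = "sbml",
                          mutations = mutation_types()) {
  out <- list()
  for (seed in seeds) {
    base <- make_base_model(dialect, n_species = 4, n_reactions = 2, seed = seed)
    for (m in mutations) {
      mut <- apply_mutation(base, m, seed = seed)
      out[[length(out) + 1L]] <- list(mutation = m, seed = seed, base = base,
                                      mutated = mut$doc, expected = mut$expected)
    }
  }
  out
}

# comparable representation of annotations (drops the delta-derived
# order_only flag, which is not part of the RDF serialization)
ann_fields <- function(anns) {
  lapply(unclass(anns), function(a) a[setdiff(names(a), "order_only")])
}

# does any annotation carry at least the expected (change, entity, targets)?
has_expected_annotation <- function(anns, expected) {
  any(vapply(anns, function(a) {
    identical(a$change_term, expected$change_term) &&
      identical(a$applies_to, expected$applies_to) &&
      all(expected$affects %in% a$affects)
  }, logical(1)))
}
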