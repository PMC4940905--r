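# Seeded generator of model version pairs with known expected annotations.
#
# The generator emulates the change classes observed in open model
# repositories: parameter retuning, typo corrections in entity names,
# network edits (species/reaction insertions and deletions), format
# specification upgrades, annotation edits and tool-induced element
# reshuffling. Every mutation carries its ground-truth expectation so that
# the full diff/annotate pipeline can be checked end to end.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

SBML_L2V4_NS <- "http://www.sbml.org/sbml/level2/version4"
SBML_L3V1_NS <- "http://www.sbml.org/sbml/level3/version1/core"
CELLML_11_NS <- "http://www.cellml.org/cellml/1.1#"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# deterministic species display names; the first carries a deliberate typo
# ("Gulcose") so that the typo_rename mutation has a canonical target
species_name_pool <- c("Gulcose", "Fructose", "Pyruvate", "Lactate", "Citrate",
                       "Acetate", "Malate", "Oxaloacetate", "Succinate", "Fumarate")

#' Generate a deterministic base model
#'
#' Builds a seeded, structurally valid core SBML Level 2 Version 4 or
#' CellML 1.1 document with unique identifiers, parameters with numeric
#' values, a kinetic law per reaction and an RDF annotation block. The same
#' `(dialect, n_species, n_reactions, seed)` always yields a byte-identical
#' document.
#'
#' @param dialect `"sbml"` or `"cellml"`.
#' @param n_species,n_reactions Non-negative counts; reactions reference
#'   existing species, so `n_reactions > 0` requires `n_species > 0`.
#' @param seed Integer seed controlling parameter values.
#' @return A `model_document`.
#' @examples
#' m <- make_base_model("sbml", n_species = 3, n_reactions = 2, seed = 1)
#' @export
make_base_model <- function(dialect = "sbml", n_species = 4, n_reactions = 2,
                            seed = 1) {
  dialect <- normalize_dialect(dialect)
  if (n_species < 0 || n_reactions < 0) {
    stop("invalid count: n_species and n_reactions must be >= 0", call. = FALSE)
  }
  if (n_reactions > 0 && n_species == 0) {
    stop("invalid count: reactions require at least one species", call. = FALSE)
  }
  if (dialect == "sbml") make_sbml_model(n_species, n_reactions, seed)
  else if (dialect == "cellml") make_cellml_model(n_species, n_reactions, seed)
  else stop("unknown dialect '", dialect, "' for fixture generation", call. = FALSE)
}

fixture_param_values <- function(n, seed) {
  with_seed(seed, sprintf("%.2f", round(stats::runif(n, 0.1, 50), 2)))
}

make_sbml_model <- function(n_species, n_reactions, seed) {
  n_params <- max(2L, n_reactions + 1L)
  pvals <- fixture_param_values(n_params, seed)
  sname <- function(i) species_name_pool[((i - 1L) %% length(species_name_pool)) + 1L]

  species <- vapply(seq_len(n_species), function(i) {
    sprintf('      <species id="S%d" metaid="meta_S%d" name="%s" compartment="cell" initialConcentration="%d"/>',
            i, i, sname(i), i)
  }, character(1))
  params <- vapply(seq_len(n_params), function(i) {
    sprintf('      <parameter id="Km%d" metaid="meta_Km%d" value="%s" units="molesperlitre"/>',
            i, i, pvals[i])
  }, character(1))
  reactions <- vapply(seq_len(n_reactions), function(i) {
    r <- ((i - 1L) %% n_species) + 1L
    p <- (i %% n_species) + 1L
    paste(
      sprintf('      <reaction id="R%d" metaid="meta_R%d" reversible="false">', i, i),
      '        <listOfReactants>',
      sprintf('          <speciesReference species="S%d"/>', r),
      '        </listOfReactants>',
      '        <listOfProducts>',
      sprintf('          <speciesReference species="S%d"/>', p),
      '        </listOfProducts>',
      '        <kineticLaw>',
      sprintf('          <math xmlns="%s">', MATHML_NS),
      '            <apply><times/>',
      sprintf('              <ci>Km%d</ci>', i),
      sprintf('              <ci>S%d</ci>', r),
      '            </apply>',
      '          </math>',
      '        </kineticLaw>',
      '      </reaction>',
      sep = "\n")
  }, character(1))

  xml <- paste(c(
    sprintf('<sbml xmlns="%s" level="2" version="4">', SBML_L2V4_NS),
    '  <model id="fixture_model" metaid="meta_model" name="Synthetic fixture model">',
    '    <annotation>',
    '      <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
    '        <rdf:Description rdf:about="#meta_model">',
    '          <bqbiol:is rdf:resource="http://identifiers.org/GO:0008152"/>',
    '        </rdf:Description>',
    '      </rdf:RDF>',
    '    </annotation>',
    '    <listOfCompartments>',
    '      <compartment id="cell" metaid="meta_cell" size="1"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    species,
    '    </listOfSpecies>',
    '    <listOfParameters>',
    params,
    '    </listOfParameters>',
    '    <listOfReactions>',
    reactions,
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), collapse = "\n")
  model_from_xml(xml, dialect = "sbml",
                 ref = sprintf("sbml-base-s%d-r%d-seed%d.xml", n_species,
                               n_reactions, seed))
}

make_cellml_model <- function(n_vars, n_components, seed) {
  n_components <- max(1L, n_components)
  vals <- fixture_param_values(max(n_vars, 1L), seed)
  comp_of <- function(i) as.integer((i - 1L) %% n_components) + 1L
  comps <- vapply(seq_len(n_components), function(ci) {
    vars <- which(vapply(seq_len(n_vars), comp_of, integer(1)) == ci)
    vlines <- vapply(vars, function(i) {
      sprintf('    <variable name="V%d" cmeta:id="meta_V%d" units="dimensionless" initial_value="%s"/>',
              i, i, vals[i])
    }, character(1))
    paste(c(
      sprintf('  <component name="comp%d" cmeta:id="meta_comp%d">', ci, ci),
      vlines,
      sprintf('    <math xmlns="%s">', MATHML_NS),
      '      <apply><eq/>',
      sprintf('        <ci>V%d</ci>', if (length(vars)) vars[1] else 1L),
      '        <cn>1</cn>',
      '      </apply>',
      '    </math>',
      '  </component>'), collapse = "\n")
  }, character(1))
  connection <- if (n_components >= 2L && n_vars >= 2L) {
    paste('  <connection>',
          '    <map_components component_1="comp1" component_2="comp2"/>',
          sprintf('    <map_variables variable_1="V%d" variable_2="V%d"/>', 1L, 2L),
          '  </connection>', sep = "\n")
  } else character()
  xml <- paste(c(
    sprintf('<model xmlns="%s" xmlns:cmeta="http://www.cellml.org/metadata/1.0#" name="fixture_model" cmeta:id="meta_model">', CELLML_11_NS),
    '  <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#">',
    '    <rdf:Description rdf:about="#meta_model">',
    '      <rdf:value>synthetic fixture model</rdf:value>',
    '    </rdf:Description>',
    '  </rdf:RDF>',
    comps,
    connection,
    '</model>'), collapse = "\n")
  model_from_xml(xml, dialect = "cellml",
                 ref = sprintf("cellml-base-v%d-c%d-seed%d.xml", n_vars,
                               n_components, seed))
}

#' Names of the scripted fixture mutations
#'
#' @return Character vector of mutation names accepted by
#'   [apply_mutation()].
#' @export
mutation_types <- function() {
  c("parameter_value_update", "typo_rename", "species_insert", "species_delete",
    "reaction_delete", "spec_upgrade", "annotation_edit", "reshuffle_parameters")
}

find_one <- function(tree, pred) {
  hits <- list()
  walk_tree(tree, function(n) if (pred(n)) hits[[length(hits) + 1L]] <<- n)
  hits
}

bump_value <- function(v) {
  # swap the two final digits when they differ (23.24 -> 23.42), else
  # increment the last digit modulo 10
  n <- nchar(v)
  if (grepl("[0-9][0-9]$", v) &&
      substr(v, n - 1L, n - 1L) != substr(v, n, n)) {
    return(paste0(substr(v, 1L, n - 2L), substr(v, n, n), substr(v, n - 1L, n - 1L)))
  }
  if (grepl("[0-9]$", v)) {
    d <- (as.integer(substr(v, n, n)) + 1L) %% 10L
    return(paste0(substr(v, 1L, n - 1L), d))
  }
  paste0(v, "1")
}

#' Apply a scripted mutation to a model
#'
#' Mutates a copy of the document and returns it together with the
#' ground-truth expectation for the annotation pipeline: the change type,
#' XML entity and target terms the mutated operation must be annotated
#' with, whether the change is order-only, and any required trigger
#' pattern.
#'
#' @param doc A `model_document` from [make_base_model()].
#' @param mutation One of [mutation_types()].
#' @param seed Integer seed for mutation-internal choices (target
#'   selection, permutations).
#' @param params Optional list of mutation-specific overrides (e.g.
#'   `parameter_id` for `parameter_value_update`).
#' @return List with elements `doc` (mutated `model_document`) and
#'   `expected` (list: `mutation`, `change_term`, `applies_to`, `affects`,
#'   `order_only`, `trigger`).
#' @export
apply_mutation <- function(doc, mutation, seed = 1, params = list()) {
  doc <- as_model_document(doc)
  mutation <- match.arg(mutation, mutation_types())
  tree <- tree_copy(doc$tree)
  dialect <- doc$dialect
  expected <- list(mutation = mutation, change_term = NA_character_,
                   applies_to = NA_character_, affects = character(),
                   order_only = FALSE, trigger = NULL)

  param_nodes <- function() {
    if (dialect == "cellml") {
      find_one(tree, function(n) n$tag == "variable" && !is.na(n$attrs["initial_value"]))
    } else {
      find_one(tree, function(n) n$tag == "parameter" && !is.na(n$attrs["value"]))
    }
  }
  pick <- function(items, what) {
    if (!length(items)) stop("target missing: no ", what, " in document", call. = FALSE)
    items[[with_seed(seed, sample.int(length(items), 1L))]]
  }

  if (mutation == "parameter_value_update") {
    attr_name <- if (dialect == "cellml") "initial_value" else "value"
    nodes <- param_nodes()
    if (!is.null(params$parameter_id)) {
      idat <- if (dialect == "cellml") "name" else "id"
      nodes <- Filter(function(n) identical(unname(n$attrs[idat]), params$parameter_id), nodes)
      if (!length(nodes)) {
        stop("target missing: no parameter with id '", params$parameter_id, "'",
             call. = FALSE)
      }
    }
    node <- pick(nodes, "parameter")
    old <- unname(node$attrs[[attr_name]])
    node$attrs[[attr_name]] <- params$new_value %||% bump_value(old)
    expected$change_term <- "Update"
    expected$applies_to <- "XmlAttribute"
    expected$affects <- "ParameterSetup"
  } else if (mutation == "typo_rename") {
    tag <- if (dialect == "cellml") "variable" else "species"
    nodes <- find_one(tree, function(n) n$tag == tag && !is.na(n$attrs["name"]))
    node <- pick(nodes, tag)
    typo <- Filter(function(n) identical(unname(n$attrs["name"]), "Gulcose"), nodes)
    if (length(typo)) node <- typo[[1]]
    old <- unname(node$attrs[["name"]])
    node$attrs[["name"]] <- if (identical(old, "Gulcose")) "Glucose" else paste0(old, "X")
    expected$change_term <- "Update"
    expected$applies_to <- "XmlAttribute"
    expected$affects <- c("EntityName",
                          if (dialect == "cellml") "ModelDefinition"
                          else "ReactionNetworkDefinition")
  } else if (mutation == "species_insert") {
    if (dialect != "sbml") stop("species_insert is defined for SBML fixtures", call. = FALSE)
    lst <- find_one(tree, function(n) n$tag == "listOfSpecies")
    if (!length(lst)) stop("target missing: no listOfSpecies", call. = FALSE)
    lst <- lst[[1]]
    i <- length(find_one(tree, function(n) n$tag == "species")) + 1L
    nm <- species_name_pool[((i + seed - 1L) %% length(species_name_pool)) + 1L]
    node <- new_tnode("species",
                      c(id = sprintf("Snew%d", i), metaid = sprintf("meta_Snew%d", i),
                        name = nm, compartment = "cell", initialConcentration = "0"),
                      parent = lst)
    lst$children <- c(lst$children, list(node))
    expected$change_term <- "Insertion"
    expected$applies_to <- "XmlNode"
    expected$affects <- "ReactionNetworkDefinition"
    expected$trigger <- list(kind = "Insertion", entity = "XmlAttribute",
                             triggered_by_tag = "species")
  } else if (mutation == "species_delete") {
    if (dialect != "sbml") stop("species_delete is defined for SBML fixtures", call. = FALSE)
    nodes <- find_one(tree, function(n) n$tag == "species")
    if (!length(nodes)) stop("target missing: no species to delete", call. = FALSE)
    node <- nodes[[length(nodes)]]
    p <- node$parent
    p$children <- p$children[!vapply(p$children, identical, logical(1), y = node)]
    expected$change_term <- "Deletion"
    expected$applies_to <- "XmlNode"
    expected$affects <- "ReactionNetworkDefinition"
    expected$trigger <- list(kind = "Deletion", entity = "XmlAttribute",
                             triggered_by_tag = "species")
  } else if (mutation == "reaction_delete") {
    if (dialect != "sbml") stop("reaction_delete is defined for SBML fixtures", call. = FALSE)
    nodes <- find_one(tree, function(n) n$tag == "reaction")
    node <- pick(nodes, "reaction")
    p <- node$parent
    p$children <- p$children[!vapply(p$children, identical, logical(1), y = node)]
    expected$change_term <- "Deletion"
    expected$applies_to <- "XmlNode"
    expected$affects <- "ReactionNetworkDefinition"
    expected$trigger <- list(kind = "Deletion", entity = "XmlNode",
                             tag = "kineticLaw", triggered_by_tag = "reaction")
  } else if (mutation == "spec_upgrade") {
    root <- tree
    if (dialect == "sbml") {
      root$attrs[["xmlns"]] <- SBML_L3V1_NS
      root$attrs[["level"]] <- "3"
      root$attrs[["version"]] <- "1"
    } else {
      root$attrs[["xmlns"]] <- "http://www.cellml.org/cellml/1.0#"
    }
    expected$change_term <- "Update"
    expected$applies_to <- "XmlAttribute"
    expected$affects <- "ModelEncoding"
  } else if (mutation == "annotation_edit") {
    nodes <- find_one(tree, function(n) {
      !is.na(n$attrs["rdf:resource"]) || (n$tag == "rdf:value" && nzchar(n$text))
    })
    if (!length(nodes)) stop("target missing: no RDF annotation", call. = FALSE)
    node <- nodes[[length(nodes)]]
    if (!is.na(node$attrs["rdf:resource"])) {
      node$attrs[["rdf:resource"]] <- paste0(unname(node$attrs[["rdf:resource"]]),
                                             "-edited")
      expected$applies_to <- "XmlAttribute"
    } else {
      node$text <- normalize_ws(paste(node$text, "edited"))
      expected$applies_to <- "XmlText"
    }
    expected$change_term <- "Update"
    expected$affects <- "ModelAnnotation"
  } else if (mutation == "reshuffle_parameters") {
    tag <- if (dialect == "cellml") "component" else "listOfParameters"
    lst <- if (dialect == "cellml") {
      comps <- find_one(tree, function(n) n$tag == "component")
      vs <- Filter(function(c) sum(vapply(c$children, function(n) n$tag == "variable",
                                          logical(1))) >= 2L, comps)
      if (!length(vs)) stop("target missing: no component with >= 2 variables", call. = FALSE)
      vs[[1]]
    } else {
      l <- find_one(tree, function(n) n$tag == "listOfParameters")
      if (!length(l) || length(l[[1]]$children) < 2L) {
        stop("target missing: need >= 2 parameters to reshuffle", call. = FALSE)
      }
      l[[1]]
    }
    n <- length(lst$children)
    perm <- with_seed(seed, sample.int(n))
    if (identical(perm, seq_len(n))) perm <- c(perm[n], perm[-n])
    lst$children <- lst$children[perm]
    expected$change_term <- "Move"
    expected$applies_to <- "XmlNode"
    expected$affects <- if (dialect == "cellml") character() else "ParameterSetup"
    expected$order_only <- dialect == "sbml"
  }

  mutated <- new_model_document(tree, dialect,
                                sub("\\.xml$", paste0("-", mutation, ".xml"), doc$ref))
  list(doc = mutated, expected = expected)
}
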