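# The COMODI change vocabulary: term hierarchy and object properties.

COMODI_BASE_IRI <- "http://purl.uni-rostock.de/comodi/comodi#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"

# id, parent, label, definition. Five root concepts (Change plus the four
# branches reachable through the object properties); Target distinguishes
# the five layers of a model document.
comodi_term_table <- function() {
  t <- function(id, parent, label, definition) {
    data.frame(id = id, parent = parent, label = label, definition = definition,
               stringsAsFactors = FALSE)
  }
  rbind(
    t("Change", NA, "Change",
      "A single difference between two versions of a model document."),
    t("Insertion", "Change", "Insertion", "An entity was added to the document."),
    t("Deletion", "Change", "Deletion", "An entity was removed from the document."),
    t("Update", "Change", "Update", "The value of an entity was modified."),
    t("Move", "Change", "Move", "An entity was relocated within the document."),
    t("XmlEntity", NA, "XML entity",
      "The kind of XML construct a change applies to."),
    t("XmlNode", "XmlEntity", "XML node", "An XML element node."),
    t("XmlAttribute", "XmlEntity", "XML attribute", "An attribute of an XML element."),
    t("XmlText", "XmlEntity", "XML text", "Text content of an XML element."),
    t("Intention", NA, "Intention",
      "The aim a change was meant to achieve, with respect to future versions."),
    t("Correction", "Intention", "Correction",
      "The change fixes something that was wrong."),
    t("Reason", NA, "Reason", "The cause that made a change necessary."),
    t("MismatchWithPublication", "Reason", "Mismatch with publication",
      "The encoded model disagreed with the published description."),
    t("Typo", "Reason", "Typo", "A typographical error in the document."),
    t("ChangedSpecification", "Reason", "Changed specification",
      "The underlying format specification changed, e.g. a new SBML level."),
    t("Target", NA, "Target", "The layer of the model document a change affects."),
    t("ModelEncoding", "Target", "Model encoding",
      "The formal encoding of the document, e.g. the format specification in use."),
    t("ModelAnnotation", "Target", "Model annotation",
      "The semantic layer: ontology links and other annotations."),
    t("ModelDefinition", "Target", "Model definition",
      "The definition of the modelled biological system."),
    t("ModelSetup", "Target", "Model setup",
      "The simulation setup, e.g. parameter values."),
    t("ModelBehaviour", "Target", "Model behaviour",
      "The dynamic behaviour of the simulated system."),
    t("EntityName", "ModelEncoding", "Entity name",
      "The human-readable name of an encoded entity."),
    t("EntityIdentifier", "ModelEncoding", "Entity identifier",
      "The machine-readable identifier of an encoded entity."),
    t("ReactionNetworkDefinition", "ModelDefinition", "Reaction network definition",
      "The species/reaction network structure of the model."),
    t("FunctionDefinition", "ModelDefinition", "Function definition",
      "A reusable mathematical function defined in the model."),
    t("KineticsDefinition", "ModelDefinition", "Kinetics definition",
      "The rate laws governing the model's reactions."),
    t("ParameterSetup", "ModelSetup", "Parameter setup",
      "The values assigned to the model's parameters.")
  )
}

comodi_property_table <- function() {
  data.frame(
    name = c("affects", "appliesTo", "hasIntention", "hasReason", "wasTriggeredBy"),
    domain = "Change",
    range = c("Target", "XmlEntity", "Intention", "Reason", "Change"),
    description = c(
      "Relates a change to the parts of the model it affects.",
      "Relates a change to the type of XML entity it was applied to.",
      "Relates a change to the intention it was meant to achieve.",
      "Relates a change to the reason that made it necessary.",
      "Relates a change to another change that triggered it."),
    stringsAsFactors = FALSE
  )
}

new_vocabulary <- function(terms, properties, version, base_iri) {
  rownames(terms) <- NULL
  rownames(properties) <- NULL
  voc <- structure(list(terms = terms, properties = properties,
                        version = version, base_iri = base_iri),
                   class = "comodi_vocabulary")
  validate_vocabulary(voc)
  voc
}

validate_vocabulary <- function(voc) {
  terms <- voc$terms
  if (anyDuplicated(terms$id)) {
    stop("duplicate term id '", terms$id[duplicated(terms$id)][1], "'", call. = FALSE)
  }
  bad <- !grepl("^[A-Za-z][A-Za-z0-9_]*$", terms$id)
  if (any(bad)) stop("invalid term id '", terms$id[bad][1], "'", call. = FALSE)
  orphan <- !is.na(terms$parent) & !(terms$parent %in% terms$id)
  if (any(orphan)) {
    stop("term '", terms$id[orphan][1], "' has unknown parent '",
         terms$parent[orphan][1], "'", call. = FALSE)
  }
  # acyclic parent chains
  for (id in terms$id) {
    seen <- character()
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cyclic parent chain at term '", id, "'", call. = FALSE)
      seen <- c(seen, cur)
      cur <- terms$parent[terms$id == cur]
    }
  }
  invisible(voc)
}

#' The built-in COMODI change vocabulary
#'
#' Returns the vocabulary used to annotate model differences: a tree of
#' terms organised into four branches around the central concept `Change`
#' (`XmlEntity`, `Intention`, `Reason`, `Target`, the latter distinguishing
#' the five layers of a model document), plus the five object properties
#' `affects`, `appliesTo`, `hasIntention`, `hasReason` and
#' `wasTriggeredBy`. The built-in set covers the core terms the annotation
#' pipeline assigns or validates; the complete released ontology can be
#' loaded with [read_owl_vocabulary()].
#'
#' @return A `comodi_vocabulary` object with components `terms` (data frame
#'   of `id`, `parent`, `label`, `definition`), `properties` (data frame of
#'   `name`, `domain`, `range`, `description`), `version` and `base_iri`.
#' @examples
#' voc <- comodi_vocabulary()
#' is_a(voc, "ParameterSetup", "ModelSetup")
#' @export
comodi_vocabulary <- function() {
  new_vocabulary(comodi_term_table(), comodi_property_table(),
                 version = "core-2016-03-11", base_iri = COMODI_BASE_IRI)
}

#' @rdname comodi_vocabulary
#' @export
load_builtin_vocabulary <- comodi_vocabulary

#' Subsumption test between vocabulary terms
#'
#' Reflexive is-a: `TRUE` iff `ancestor` equals `term` or lies on its
#' parent chain. A change affecting `ParameterSetup`, for instance, also
#' affects its ancestor `ModelSetup`.
#'
#' @param voc A `comodi_vocabulary`.
#' @param term,ancestor Term ids.
#' @return Logical scalar.
#' @export
is_a <- function(voc, term, ancestor) {
  stopifnot(inherits(voc, "comodi_vocabulary"))
  for (id in c(term, ancestor)) {
    if (!(id %in% voc$terms$id)) {
      stop("unknown term '", id, "' in vocabulary", call. = FALSE)
    }
  }
  cur <- term
  while (!is.na(cur)) {
    if (identical(cur, ancestor)) return(TRUE)
    cur <- voc$terms$parent[voc$terms$id == cur]
  }
  FALSE
}

vocab_root <- function(voc, term) {
  cur <- term
  repeat {
    p <- voc$terms$parent[voc$terms$id == cur]
    if (is.na(p)) return(cur)
    cur <- p
  }
}

term_children <- function(voc, term) {
  voc$terms$id[!is.na(voc$terms$parent) & voc$terms$parent == term]
}

#' Ancestors of a term (including itself)
#'
#' @param voc A `comodi_vocabulary`.
#' @param term A term id.
#' @return Character vector from `term` up to its root concept.
#' @export
term_ancestors <- function(voc, term) {
  if (!(term %in% voc$terms$id)) stop("unknown term '", term, "'", call. = FALSE)
  out <- character()
  cur <- term
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- voc$terms$parent[voc$terms$id == cur]
  }
  out
}

#' @export
print.comodi_vocabulary <- function(x, ...) {
  roots <- x$terms$id[is.na(x$terms$parent)]
  cat(sprintf("<comodi_vocabulary> version %s: %d terms, %d object properties\n",
              x$version, nrow(x$terms), nrow(x$properties)))
  cat("  roots:", paste(roots, collapse = ", "), "\n")
  invisible(x)
}

# -- Turtle / OWL interchange --------------------------------------------

#' Export a vocabulary as Turtle
#'
#' Each term becomes an `owl:Class` with an `rdfs:subClassOf` triple to its
#' parent; each object property an `owl:ObjectProperty` with domain and
#' range. The output re-parses to an equal vocabulary with
#' [vocabulary_from_turtle()].
#'
#' @param voc A `comodi_vocabulary`.
#' @return Turtle text as a single string.
#' @export
vocabulary_to_turtle <- function(voc) {
  stopifnot(inherits(voc, "comodi_vocabulary"))
  lines <- c(
    sprintf("@prefix comodi: <%s> .", voc$base_iri),
    sprintf("@prefix rdf: <%s> .", RDF_NS),
    sprintf("@prefix rdfs: <%s> .", RDFS_NS),
    sprintf("@prefix owl: <%s> .", OWL_NS),
    "",
    sprintf("<%s> rdf:type owl:Ontology ;", sub("#$", "", voc$base_iri)),
    sprintf("    owl:versionInfo %s .", ttl_literal(voc$version)),
    ""
  )
  for (i in seq_len(nrow(voc$terms))) {
    tm <- voc$terms[i, ]
    body <- c(sprintf("comodi:%s rdf:type owl:Class", tm$id),
              sprintf("    rdfs:label %s", ttl_literal(tm$label)),
              if (nzchar(tm$definition %||% "")) {
                sprintf("    rdfs:comment %s", ttl_literal(tm$definition))
              },
              if (!is.na(tm$parent)) sprintf("    rdfs:subClassOf comodi:%s", tm$parent))
    lines <- c(lines, paste0(paste(body, collapse = " ;\n"), " ."), "")
  }
  for (i in seq_len(nrow(voc$properties))) {
    pr <- voc$properties[i, ]
    body <- c(sprintf("comodi:%s rdf:type owl:ObjectProperty", pr$name),
              sprintf("    rdfs:comment %s", ttl_literal(pr$description)),
              sprintf("    rdfs:domain comodi:%s", pr$domain),
              sprintf("    rdfs:range comodi:%s", pr$range))
    lines <- c(lines, paste0(paste(body, collapse = " ;\n"), " ."), "")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a Turtle-encoded vocabulary
#'
#' Inverse of [vocabulary_to_turtle()]; also reads other Turtle renderings
#' that express the hierarchy through `owl:Class`/`rdfs:subClassOf` and the
#' properties through `owl:ObjectProperty` with `rdfs:domain`/`rdfs:range`.
#'
#' @param text Turtle text (or a file path).
#' @param base_iri Namespace of the vocabulary terms; local names are
#'   formed by stripping it.
#' @return A `comodi_vocabulary`.
#' @export
vocabulary_from_turtle <- function(text, base_iri = COMODI_BASE_IRI) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  g <- parse_turtle(text)
  tr <- g$triples
  localize <- function(iri) sub(base_iri, "", iri, fixed = TRUE)
  type_p <- paste0(RDF_NS, "type")
  classes <- localize(tr$s[tr$p == type_p & tr$o == paste0(OWL_NS, "Class")])
  objprops <- localize(tr$s[tr$p == type_p & tr$o == paste0(OWL_NS, "ObjectProperty")])
  get1 <- function(s, p, default = NA_character_) {
    hit <- tr$o[tr$s == paste0(base_iri, s) & tr$p == p]
    if (length(hit)) hit[1] else default
  }
  terms <- do.call(rbind, lapply(classes, function(id) {
    parent <- get1(id, paste0(RDFS_NS, "subClassOf"))
    data.frame(id = id,
               parent = if (is.na(parent)) NA_character_ else localize(parent),
               label = get1(id, paste0(RDFS_NS, "label"), id),
               definition = get1(id, paste0(RDFS_NS, "comment"), ""),
               stringsAsFactors = FALSE)
  })) %||% data.frame(id = character(), parent = character(),
                      label = character(), definition = character())
  props <- do.call(rbind, lapply(objprops, function(nm) {
    data.frame(name = nm,
               domain = localize(get1(nm, paste0(RDFS_NS, "domain"))),
               range = localize(get1(nm, paste0(RDFS_NS, "range"))),
               description = get1(nm, paste0(RDFS_NS, "comment"), ""),
               stringsAsFactors = FALSE)
  })) %||% data.frame(name = character(), domain = character(),
                      range = character(), description = character())
  version <- {
    hit <- tr$o[tr$p == paste0(OWL_NS, "versionInfo")]
    if (length(hit)) hit[1] else "unversioned"
  }
  new_vocabulary(terms[order(match(terms$id, comodi_term_table()$id),
                             terms$id), , drop = FALSE],
                 props[order(match(props$name, comodi_property_table()$name),
                             props$name), , drop = FALSE],
                 version, base_iri)
}

#' Load a vocabulary from an OWL (RDF/XML) file
#'
#' Reads `owl:Class` and `owl:ObjectProperty` declarations with their
#' `rdfs:subClassOf`, label, comment, domain and range, e.g. from the
#' released COMODI OWL file. Anonymous (blank-node) class axioms such as
#' restrictions are ignored.
#'
#' @param path Path to an RDF/XML OWL file.
#' @param base_iri Namespace of the vocabulary terms.
#' @return A `comodi_vocabulary`.
#' @export
read_owl_vocabulary <- function(path, base_iri = COMODI_BASE_IRI) {
  doc <- xml2::read_xml(path)
  ns <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS)
  localize <- function(iri) sub(base_iri, "", iri, fixed = TRUE)
  about <- function(node) {
    v <- xml2::xml_attr(node, "rdf:about", ns = ns)
    if (is.na(v)) xml2::xml_attr(node, "rdf:ID", ns = ns) else v
  }
  child_txt <- function(node, xp) {
    hit <- xml2::xml_find_first(node, xp, ns = ns)
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }
  child_res <- function(node, xp) {
    hit <- xml2::xml_find_first(node, xp, ns = ns)
    if (inherits(hit, "xml_missing")) NA_character_
    else xml2::xml_attr(hit, "rdf:resource", ns = ns)
  }
  cls <- xml2::xml_find_all(doc, "//owl:Class[@rdf:about or @rdf:ID]", ns = ns)
  terms <- do.call(rbind, lapply(cls, function(node) {
    id <- localize(about(node))
    parent <- child_res(node, "./rdfs:subClassOf")
    data.frame(id = id,
               parent = if (is.na(parent)) NA_character_ else localize(parent),
               label = child_txt(node, "./rdfs:label") %||% id,
               definition = child_txt(node, "./rdfs:comment") %||% "",
               stringsAsFactors = FALSE)
  })) %||% data.frame(id = character(), parent = character(),
                      label = character(), definition = character())
  terms$label[is.na(terms$label)] <- terms$id[is.na(terms$label)]
  terms$definition[is.na(terms$definition)] <- ""
  prps <- xml2::xml_find_all(doc, "//owl:ObjectProperty[@rdf:about or @rdf:ID]", ns = ns)
  props <- do.call(rbind, lapply(prps, function(node) {
    data.frame(name = localize(about(node)),
               domain = localize(child_res(node, "./rdfs:domain")),
               range = localize(child_res(node, "./rdfs:range")),
               description = child_txt(node, "./rdfs:comment") %||% "",
               stringsAsFactors = FALSE)
  })) %||% data.frame(name = character(), domain = character(),
                      range = character(), description = character())
  props$description[is.na(props$description)] <- ""
  version <- child_txt(doc, "//owl:Ontology/owl:versionInfo") %||% "unversioned"
  new_vocabulary(terms, props, version, base_iri)
}
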