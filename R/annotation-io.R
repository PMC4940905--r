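# RDF/Turtle serialization of change annotations.
#
# Annotations are stored independently of the diff XML: each change is an
# IRI formed as <delta reference>#<operation id>, typed with its Change
# subclass and linked to vocabulary terms through the five object
# properties. No blank nodes are emitted and the prefix set is fixed, so
# output is byte-stable.

#' Write change annotations as Turtle
#'
#' @param annotations A `change_annotations` object.
#' @param delta_ref Reference to the diff XML file the annotations describe
#'   (relative or absolute IRI); operation IRIs are `delta_ref#op_id`.
#' @param base_iri Vocabulary namespace bound to the `comodi:` prefix.
#' @param path Optional output file.
#' @param vocabulary Vocabulary used to validate term ranges before any
#'   output is produced.
#' @return Turtle text as a single string (invisibly when `path` is given).
#' @examples
#' \dontrun{
#' annotations_to_turtle(anns, delta_ref = "delta.xml")
#' }
#' @export
annotations_to_turtle <- function(annotations, delta_ref = "delta.xml",
                                  base_iri = COMODI_BASE_IRI, path = NULL,
                                  vocabulary = comodi_vocabulary()) {
  for (ann in annotations) validate_annotation_terms(ann, vocabulary)
  lines <- c(
    sprintf("@prefix comodi: <%s> .", base_iri),
    sprintf("@prefix rdf: <%s> .", RDF_NS),
    ""
  )
  for (ann in annotations) {
    subj <- sprintf("<%s#%s>", delta_ref, ann$op_id)
    stmts <- c(
      sprintf("rdf:type comodi:%s", ann$change_term),
      sprintf("comodi:appliesTo comodi:%s", ann$applies_to),
      sprintf("comodi:affects comodi:%s", ann$affects),
      sprintf("comodi:hasIntention comodi:%s", ann$has_intention),
      sprintf("comodi:hasReason comodi:%s", ann$has_reason),
      sprintf("comodi:wasTriggeredBy <%s#%s>", delta_ref, ann$was_triggered_by)
    )
    body <- paste0(subj, " ", paste(stmts, collapse = " ;\n    "), " .")
    lines <- c(lines, body, "")
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' Read change annotations from Turtle
#'
#' Inverse of [annotations_to_turtle()]. Triples whose predicate is not one
#' of the five vocabulary object properties (or `rdf:type`), and term IRIs
#' outside the vocabulary, are collected into a warning list attached as
#' attribute `"warnings"` (and raised as an R warning), never silently
#' dropped.
#'
#' @param text Turtle text or a file path.
#' @param vocabulary The vocabulary used to resolve and validate terms.
#' @param delta Optional `model_delta`: when given, the `order_only` flag
#'   of each annotation (not part of the RDF) is recomputed from the delta.
#' @return A `change_annotations` object with a `"warnings"` attribute.
#' @export
annotations_from_turtle <- function(text, vocabulary = comodi_vocabulary(),
                                    delta = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  g <- parse_turtle(text)
  tr <- g$triples
  base_iri <- vocabulary$base_iri
  warnings <- character()
  localize <- function(iri) sub(base_iri, "", iri, fixed = TRUE)

  known_props <- vocabulary$properties$name
  prop_of <- function(p) {
    if (p == paste0(RDF_NS, "type")) return("rdf:type")
    if (startsWith(p, base_iri) && localize(p) %in% known_props) return(localize(p))
    NA_character_
  }

  subjects <- unique(tr$s)
  anns <- list()
  for (s in subjects) {
    op_id <- sub("^.*#", "", s)
    rows <- tr[tr$s == s, , drop = FALSE]
    fields <- list(change_term = character(), applies_to = character(),
                   affects = character(), has_intention = character(),
                   has_reason = character(), was_triggered_by = character())
    for (j in seq_len(nrow(rows))) {
      p <- prop_of(rows$p[j])
      o <- rows$o[j]
      if (is.na(p)) {
        warnings <- c(warnings, sprintf("unknown predicate <%s> on %s", rows$p[j], s))
        next
      }
      if (p == "wasTriggeredBy") {
        fields$was_triggered_by <- c(fields$was_triggered_by, sub("^.*#", "", o))
        next
      }
      term <- localize(o)
      if (!startsWith(o, base_iri) || !(term %in% vocabulary$terms$id)) {
        warnings <- c(warnings, sprintf("unknown term <%s> for %s on %s", o, p, s))
        next
      }
      slot <- switch(p, "rdf:type" = "change_term", "appliesTo" = "applies_to",
                     "affects" = "affects", "hasIntention" = "has_intention",
                     "hasReason" = "has_reason")
      fields[[slot]] <- c(fields[[slot]], term)
    }
    if (!length(fields$change_term) && !length(fields$applies_to)) next
    anns[[length(anns) + 1L]] <- new_change_annotation(
      op_id = op_id,
      change_term = fields$change_term[1] %||% NA_character_,
      applies_to = fields$applies_to[1] %||% NA_character_,
      affects = sort(unique(fields$affects)),
      has_intention = sort(unique(fields$has_intention)),
      has_reason = sort(unique(fields$has_reason)),
      was_triggered_by = sort(unique(fields$was_triggered_by)),
      order_only = FALSE)
  }
  ord <- order(vapply(anns, function(a) {
    suppressWarnings(as.integer(sub("^op", "", a$op_id))) %||% NA_integer_
  }, integer(1)), vapply(anns, function(a) a$op_id, character(1)))
  anns <- anns[ord]
  if (!is.null(delta)) {
    ops <- stats::setNames(delta$operations,
                           vapply(delta$operations, function(o) o$op_id, character(1)))
    for (i in seq_along(anns)) {
      op <- ops[[anns[[i]]$op_id]]
      if (!is.null(op)) {
        anns[[i]]$order_only <- is_order_only(op, delta$dialect)
      }
    }
  }
  if (length(warnings)) {
    warning("annotations contained ", length(warnings),
            " unrecognised element(s); see attr(, 'warnings')", call. = FALSE)
  }
  structure(anns, class = c("change_annotations", "list"), warnings = warnings)
}
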