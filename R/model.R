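# Reading model documents and dialect detection.

SBML_NS_PREFIX <- "http://www.sbml.org/sbml/"
CELLML_NS_PREFIX <- "http://www.cellml.org/cellml/"

detect_dialect <- function(tree) {
  nm <- names(tree$attrs) %||% character()
  ns <- unname(tree$attrs[nm == "xmlns" | startsWith(nm, "xmlns:")])
  local <- sub("^[^:]+:", "", tree$tag)
  if (local == "sbml" || any(startsWith(ns, SBML_NS_PREFIX))) return("sbml")
  if (local == "model" && any(startsWith(ns, CELLML_NS_PREFIX))) return("cellml")
  "generic"
}

new_model_document <- function(tree, dialect, ref) {
  structure(list(tree = tree, dialect = dialect, ref = ref),
            class = "model_document")
}

#' Read an XML model document
#'
#' Parses an SBML, CellML or generic XML document into the internal form
#' used by the diff engine. The dialect (which controls identity attributes
#' for node matching, target classification rules and unordered-container
#' lists) is detected from the root element namespace unless given.
#'
#' @param path Path to an XML file.
#' @param dialect `"auto"` (default), `"sbml"`, `"cellml"` or `"generic"`.
#' @return A `model_document` object.
#' @seealso [model_from_xml()] for in-memory strings, [diff_models()].
#' @export
read_model <- function(path, dialect = "auto") {
  x <- tryCatch(xml2::read_xml(path),
                error = function(e) stop("malformed document '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  tree <- xml_to_tree(x)
  if (identical(dialect, "auto")) dialect <- detect_dialect(tree)
  dialect <- normalize_dialect(dialect)
  new_model_document(tree, dialect, basename(path))
}

#' Parse an XML string into a model document
#'
#' @param text Length-1 character string of XML.
#' @param dialect See [read_model()].
#' @param ref Opaque document identifier recorded in deltas.
#' @return A `model_document` object.
#' @export
model_from_xml <- function(text, dialect = "auto", ref = "memory") {
  x <- tryCatch(xml2::read_xml(text),
                error = function(e) stop("malformed document: ",
                                         conditionMessage(e), call. = FALSE))
  tree <- xml_to_tree(x)
  if (identical(dialect, "auto")) dialect <- detect_dialect(tree)
  new_model_document(tree, normalize_dialect(dialect), ref)
}

normalize_dialect <- function(dialect) {
  d <- match.arg(dialect, c("sbml", "cellml", "generic", "generic-xml"))
  if (d == "generic-xml") "generic" else d
}

as_model_document <- function(doc) {
  if (inherits(doc, "model_document")) return(doc)
  if (inherits(doc, "xml_document") || inherits(doc, "xml_node")) {
    tree <- xml_to_tree(doc)
    return(new_model_document(tree, detect_dialect(tree), "memory"))
  }
  if (is.character(doc) && length(doc) == 1L) {
    if (file.exists(doc) && !grepl("<", doc, fixed = TRUE)) return(read_model(doc))
    return(model_from_xml(doc))
  }
  stop("cannot interpret object of class '", paste(class(doc), collapse = "/"),
       "' as a model document", call. = FALSE)
}

#' Serialize a model document back to XML text
#'
#' @param doc A `model_document`.
#' @param pretty Indent output for readability.
#' @return A character string of XML.
#' @export
model_to_xml <- function(doc, pretty = TRUE) {
  tree_to_xml(as_model_document(doc)$tree, pretty = pretty)
}

#' Write a model document to a file
#'
#' @param doc A `model_document`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(doc, path) {
  writeLines(model_to_xml(doc), path)
  invisible(path)
}

#' @export
print.model_document <- function(x, ...) {
  n <- 0L
  walk_tree(x$tree, function(nd) n <<- n + 1L)
  cat(sprintf("<model_document> dialect=%s ref=%s root=<%s> elements=%d\n",
              x$dialect, x$ref, x$tree$tag, n))
  invisible(x)
}
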