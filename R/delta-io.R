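# Diff XML serialization of deltas.
#
# Dialect: a <modelDiff> root carrying document references and the model
# dialect, one <operation> element per change. Addresses are slash-separated
# tag[k] steps (k = 1-based index among same-tag siblings); afterB/orderB
# record the insertion anchor and the document order in version B so that
# patching is deterministic.

DIFF_NS <- "https://comodiff.r-lib.org/modeldiff"

#' Serialize a delta as diff XML
#'
#' @param delta A `model_delta`.
#' @param path Optional output file; when `NULL` the XML text is returned.
#' @return The diff XML as a character string (invisibly when `path` is
#'   given).
#' @export
write_delta <- function(delta, path = NULL) {
  stopifnot(inherits(delta, "model_delta"))
  doc <- xml2::xml_new_root("modelDiff", xmlns = DIFF_NS,
                            docA = delta$doc_a_ref, docB = delta$doc_b_ref,
                            dialect = delta$dialect)
  for (op in delta$operations) {
    at <- list(id = op$op_id, kind = op$kind, entity = op$entity_kind)
    if (!is.na(op$address_a)) at$addressA <- op$address_a
    if (!is.na(op$address_b)) at$addressB <- op$address_b
    if (!is.na(op$attribute)) at$attribute <- op$attribute
    if (!is.na(op$old_value)) at$oldValue <- op$old_value
    if (!is.na(op$new_value)) at$newValue <- op$new_value
    if (!is.na(op$after_b)) at$afterB <- op$after_b
    if (!is.na(op$order_b)) at$orderB <- as.character(op$order_b)
    if (length(op$triggered_by)) at$triggeredBy <- paste(op$triggered_by, collapse = " ")
    do.call(xml2::xml_add_child, c(list(doc, "operation"), at))
  }
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

op_field <- function(attrs, name) {
  if (name %in% names(attrs)) unname(attrs[[name]]) else NA_character_
}

#' Parse diff XML back into a delta
#'
#' Validates the structural rules of each operation kind (Insertions carry
#' no source address or old value, Deletions no target address or new
#' value, Updates both values with old != new, Moves both addresses) and
#' fails listing every offending operation.
#'
#' @param x Diff XML text or a file path.
#' @return A `model_delta`.
#' @export
read_delta <- function(x) {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) stop("malformed diff XML: ",
                                           conditionMessage(e), call. = FALSE))
  root_attrs <- xml2::xml_attrs(doc)
  ops <- list()
  problems <- character()
  for (node in xml2::xml_find_all(doc, "./*")) {
    if (xml2::xml_name(node) != "operation") next
    a <- xml2::xml_attrs(node)
    op <- new_op(op_field(a, "kind"), op_field(a, "entity"),
                 address_a = op_field(a, "addressA"),
                 address_b = op_field(a, "addressB"),
                 attribute = op_field(a, "attribute"),
                 old_value = op_field(a, "oldValue"),
                 new_value = op_field(a, "newValue"),
                 after_b = op_field(a, "afterB"),
                 order_b = {
                   ob <- op_field(a, "orderB")
                   if (is.na(ob)) NA_integer_ else as.integer(ob)
                 })
    op$op_id <- op_field(a, "id")
    tb <- op_field(a, "triggeredBy")
    if (!is.na(tb)) op$triggered_by <- strsplit(tb, " +")[[1]]
    problems <- c(problems, validate_op(op))
    ops[[length(ops) + 1L]] <- op
  }
  ids <- vapply(ops, function(o) o$op_id, character(1))
  if (anyDuplicated(ids)) {
    problems <- c(problems, sprintf("duplicate operation id '%s'",
                                    ids[duplicated(ids)][1]))
  }
  known <- ids[!is.na(ids)]
  for (op in ops) {
    miss <- setdiff(op$triggered_by, known)
    if (length(miss)) {
      problems <- c(problems, sprintf("operation %s triggeredBy unknown id(s) %s",
                                      op$op_id, paste(miss, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("diff XML violates the operation schema:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(operations = ops,
                 doc_a_ref = op_field(root_attrs, "docA"),
                 doc_b_ref = op_field(root_attrs, "docB"),
                 dialect = op_field(root_attrs, "dialect")),
            class = "model_delta")
}

validate_op <- function(op) {
  p <- character()
  id <- op$op_id %||% "?"
  if (is.na(op$kind) || !(op$kind %in% c("Insertion", "Deletion", "Update", "Move"))) {
    return(sprintf("operation %s: unknown kind '%s'", id, op$kind))
  }
  if (is.na(op$entity_kind) ||
      !(op$entity_kind %in% c("XmlNode", "XmlAttribute", "XmlText"))) {
    return(sprintf("operation %s: unknown entity '%s'", id, op$entity_kind))
  }
  if (op$kind == "Insertion") {
    if (!is.na(op$address_a) || !is.na(op$old_value)) {
      p <- c(p, sprintf("operation %s: Insertion must not carry addressA/oldValue", id))
    }
    if (is.na(op$address_b)) {
      p <- c(p, sprintf("operation %s: Insertion requires addressB", id))
    }
  } else if (op$kind == "Deletion") {
    if (!is.na(op$address_b) || !is.na(op$new_value)) {
      p <- c(p, sprintf("operation %s: Deletion must not carry addressB/newValue", id))
    }
    if (is.na(op$address_a)) {
      p <- c(p, sprintf("operation %s: Deletion requires addressA", id))
    }
  } else if (op$kind == "Update") {
    if (is.na(op$old_value) || is.na(op$new_value) ||
        identical(op$old_value, op$new_value)) {
      p <- c(p, sprintf("operation %s: Update requires oldValue != newValue", id))
    }
    if (is.na(op$address_a)) {
      p <- c(p, sprintf("operation %s: Update requires addressA", id))
    }
  } else if (op$kind == "Move") {
    if (is.na(op$address_a) || is.na(op$address_b)) {
      p <- c(p, sprintf("operation %s: Move requires both addresses", id))
    }
  }
  p
}
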