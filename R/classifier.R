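# Automatic annotation of change operations with vocabulary terms.
#
# Only the XmlEntity and Target branches are assigned automatically;
# Intention and Reason always come from the user. Target assignment is
# rule-table driven (packaged TSV per dialect, user-replaceable): element
# rules fire for the nearest enclosing construct that has one (walking the
# address from the changed element upwards), attribute and namespace rules
# add further terms for the changed attribute.

#' Load a target classification rule table
#'
#' Rule tables are tab-separated files with columns `kind`
#' (`element`/`attribute`/`namespace`), `tag`, `attribute` (`*` = any) and
#' `targets` (space-separated term ids under `Target`). The packaged
#' defaults for SBML and CellML live in the package's `extdata` directory.
#'
#' @param dialect `"sbml"` or `"cellml"`, or a path to a custom TSV file.
#' @return A data frame of rules.
#' @export
target_rules <- function(dialect) {
  path <- if (file.exists(dialect)) {
    dialect
  } else {
    d <- normalize_dialect(dialect)
    if (d == "generic") return(data.frame(kind = character(), tag = character(),
                                          attribute = character(), targets = character()))
    system.file("extdata", sprintf("target_rules_%s.tsv", d),
                package = "comodiff", mustWork = TRUE)
  }
  rules <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("kind", "tag", "attribute", "targets")
  if (!all(need %in% names(rules))) {
    stop("rule table '", path, "' lacks columns ",
         paste(setdiff(need, names(rules)), collapse = ", "), call. = FALSE)
  }
  voc <- comodi_vocabulary()
  for (tm in unlist(strsplit(rules$targets, " +"))) {
    if (!is_a(voc, tm, "Target")) {
      stop("rule table term '", tm, "' is not subsumed by Target", call. = FALSE)
    }
  }
  rules
}

op_owner_path <- function(op) {
  if (!is.na(op$address_a)) op$address_a else op$address_b
}

is_namespace_attr <- function(name) {
  !is.na(name) && (name == "xmlns" || startsWith(name, "xmlns:"))
}

#' Classify the XML entity of a change operation
#'
#' @param op A `change_op` (element of a `model_delta`).
#' @return `"XmlAttribute"`, `"XmlText"` or `"XmlNode"`.
#' @export
classify_entity <- function(op) {
  if (!is.na(op$attribute)) "XmlAttribute"
  else if (identical(op$entity_kind, "XmlText")) "XmlText"
  else "XmlNode"
}

#' Classify the model-layer targets of a change operation
#'
#' Returns the stored target terms (most specific) for the change; the
#' ancestors up to `Target` are implied by subsumption at query time (see
#' [is_a()]), not stored.
#'
#' @param op A `change_op`.
#' @param dialect `"sbml"`, `"cellml"` or `"generic"` (no rules).
#' @param rules Optional rule table from [target_rules()].
#' @return Character vector of term ids under `Target` (possibly empty).
#' @examples
#' d <- diff_models(
#'   '<sbml xmlns="http://www.sbml.org/sbml/level2/version4"><model>
#'      <listOfParameters><parameter id="Km1" value="23.24"/></listOfParameters>
#'    </model></sbml>',
#'   '<sbml xmlns="http://www.sbml.org/sbml/level2/version4"><model>
#'      <listOfParameters><parameter id="Km1" value="23.42"/></listOfParameters>
#'    </model></sbml>')
#' classify_target(d$operations[[1]], "sbml")
#' @export
classify_target <- function(op, dialect, rules = NULL) {
  if (is.null(rules)) rules <- target_rules(dialect)
  targets <- character()
  tags <- address_tags(op_owner_path(op))
  ent <- classify_entity(op)

  if (ent == "XmlAttribute") {
    if (is_namespace_attr(op$attribute)) {
      hit <- rules[rules$kind == "namespace", , drop = FALSE]
      targets <- c(targets, unlist(strsplit(hit$targets, " +")))
    } else {
      owner <- tags[length(tags)]
      hit <- rules[rules$kind == "attribute" & rules$attribute == op$attribute &
                     (rules$tag == "*" | rules$tag == owner), , drop = FALSE]
      targets <- c(targets, unlist(strsplit(hit$targets, " +")))
    }
  }
  # nearest enclosing construct with an element rule
  erules <- rules[rules$kind == "element", , drop = FALSE]
  for (tg in rev(tags)) {
    hit <- erules[erules$tag == tg, , drop = FALSE]
    if (nrow(hit)) {
      targets <- c(targets, unlist(strsplit(hit$targets, " +")))
      break
    }
  }
  sort(unique(targets))
}

#' Infer wasTriggeredBy links between operations of a delta
#'
#' Deleting an XML node triggers the deletion of its attributes, its text
#' and its child nodes (and so on down the subtree, forming a chain);
#' inserting a node likewise triggers the insertions it entails. The
#' populated trigger graph is a forest and therefore acyclic; a cycle
#' indicates an internal inconsistency and raises an error.
#'
#' @param delta A `model_delta`.
#' @return The delta with `triggered_by` populated (idempotent).
#' @export
infer_triggers <- function(delta) {
  stopifnot(inherits(delta, "model_delta"))
  ops <- delta$operations
  node_by_addr <- function(kind, addr_field) {
    idx <- new.env(parent = emptyenv())
    for (op in ops) {
      if (op$kind == kind && op$entity_kind == "XmlNode" && !is.na(op[[addr_field]])) {
        idx[[op[[addr_field]]]] <- op$op_id
      }
    }
    idx
  }
  del_nodes <- node_by_addr("Deletion", "address_a")
  ins_nodes <- node_by_addr("Insertion", "address_b")

  for (i in seq_along(ops)) {
    op <- ops[[i]]
    trigger <- NULL
    if (op$kind == "Deletion") {
      owner <- if (op$entity_kind == "XmlNode") address_parent(op$address_a)
               else op$address_a
      trigger <- del_nodes[[owner]]
    } else if (op$kind == "Insertion") {
      owner <- if (op$entity_kind == "XmlNode") address_parent(op$address_b)
               else op$address_b
      trigger <- ins_nodes[[owner]]
    }
    if (!is.null(trigger) && !identical(trigger, op$op_id)) {
      ops[[i]]$triggered_by <- sort(union(op$triggered_by, trigger))
    }
  }
  delta$operations <- ops
  assert_acyclic_triggers(ops)
  delta
}

assert_acyclic_triggers <- function(ops) {
  ids <- vapply(ops, function(o) o$op_id, character(1))
  edges <- lapply(ops, function(o) o$triggered_by)
  names(edges) <- ids
  state <- new.env(parent = emptyenv())  # 1 = visiting, 2 = done
  visit <- function(id) {
    st <- state[[id]]
    if (identical(st, 2L)) return(invisible())
    if (identical(st, 1L)) stop("cycle in the trigger graph at ", id, call. = FALSE)
    state[[id]] <- 1L
    for (nxt in edges[[id]]) if (nxt %in% ids) visit(nxt)
    state[[id]] <- 2L
  }
  for (id in ids) visit(id)
  invisible(TRUE)
}

# -- full annotation -----------------------------------------------------

new_change_annotation <- function(op_id, change_term, applies_to, affects,
                                  has_intention = character(),
                                  has_reason = character(),
                                  was_triggered_by = character(),
                                  order_only = FALSE) {
  structure(list(op_id = op_id, change_term = change_term,
                 applies_to = applies_to, affects = affects,
                 has_intention = has_intention, has_reason = has_reason,
                 was_triggered_by = was_triggered_by, order_only = order_only),
            class = "change_annotation")
}

validate_annotation_terms <- function(ann, voc) {
  check <- function(terms, range, property) {
    for (tm in terms) {
      if (!(tm %in% voc$terms$id)) {
        stop(sprintf("unknown term '%s' for property %s", tm, property),
             call. = FALSE)
      }
      if (!is_a(voc, tm, range)) {
        stop(sprintf("range violation: property %s requires a term under %s, got '%s'",
                     property, range, tm), call. = FALSE)
      }
    }
  }
  ranges <- stats::setNames(voc$properties$range, voc$properties$name)
  check(ann$change_term, "Change", "rdf:type")
  check(ann$applies_to, ranges[["appliesTo"]], "appliesTo")
  check(ann$affects, ranges[["affects"]], "affects")
  check(ann$has_intention, ranges[["hasIntention"]], "hasIntention")
  check(ann$has_reason, ranges[["hasReason"]], "hasReason")
  invisible(ann)
}

#' Annotate every operation of a delta with vocabulary terms
#'
#' For each operation the change type (`Insertion`/`Deletion`/`Update`/
#' `Move`), the XML entity ([classify_entity()]) and the affected model
#' layers ([classify_target()]) are assigned automatically, and trigger
#' links are copied from the delta. Intention and Reason terms (and
#' optionally additional `affects` terms such as `ModelBehaviour`, which is
#' never assigned automatically) are taken from `user_annotations` only.
#'
#' @param delta A `model_delta`.
#' @param dialect Overrides the delta's dialect.
#' @param user_annotations Named list: `op_id -> list(has_intention =,
#'   has_reason =, affects =)`, each a character vector of term ids. Terms
#'   must respect the object-property ranges of the vocabulary.
#' @param vocabulary The vocabulary to validate against.
#' @return A `change_annotations` object (list of `change_annotation`).
#' @export
annotate_delta <- function(delta, dialect = NULL, user_annotations = NULL,
                           vocabulary = comodi_vocabulary()) {
  stopifnot(inherits(delta, "model_delta"))
  dialect <- normalize_dialect(dialect %||% delta$dialect)
  rules <- target_rules(dialect)
  delta <- infer_triggers(delta)
  known_ids <- vapply(delta$operations, function(o) o$op_id, character(1))
  for (uid in names(user_annotations) %||% character()) {
    if (!(uid %in% known_ids)) {
      stop("user annotation for unknown operation id '", uid, "'", call. = FALSE)
    }
  }
  anns <- lapply(delta$operations, function(op) {
    user <- user_annotations[[op$op_id]] %||% list()
    ann <- new_change_annotation(
      op_id = op$op_id,
      change_term = op$kind,
      applies_to = classify_entity(op),
      affects = sort(unique(c(classify_target(op, dialect, rules),
                              user$affects %||% character()))),
      has_intention = sort(unique(user$has_intention %||% character())),
      has_reason = sort(unique(user$has_reason %||% character())),
      was_triggered_by = op$triggered_by,
      order_only = is_order_only(op, dialect))
    validate_annotation_terms(ann, vocabulary)
    ann
  })
  structure(anns, class = c("change_annotations", "list"))
}

#' @export
print.change_annotation <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ",") else "-"
  cat(sprintf("%s %s appliesTo=%s affects=%s intention=%s reason=%s%s%s\n",
              x$op_id, x$change_term, x$applies_to, fmt(x$affects),
              fmt(x$has_intention), fmt(x$has_reason),
              if (length(x$was_triggered_by))
                paste0(" triggeredBy=", fmt(x$was_triggered_by)) else "",
              if (isTRUE(x$order_only)) " [order-only]" else ""))
  invisible(x)
}

#' @export
print.change_annotations <- function(x, n = 20L, ...) {
  cat(sprintf("<change_annotations> %d annotated changes\n", length(x)))
  for (ann in utils::head(x, n)) { cat("  "); print(ann) }
  if (length(x) > n) cat(sprintf("  ... %d more\n", length(x) - n))
  invisible(x)
}
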