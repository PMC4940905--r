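# Tree matching and delta computation.
#
# The matcher is id-anchored and greedy: model formats carry stable
# identifiers (SBML "id"/"metaid", CellML "name"/"cmeta:id"), so a global
# identity pass matches most entities even across container moves; the
# remainder is matched structurally under already-matched parents by
# (tag, name attribute) and finally by position among unmatched same-tag
# siblings. No optimal tree-edit-distance search is attempted.

dialect_id_attrs <- function(dialect) {
  switch(dialect,
         sbml = c("id", "metaid"),
         cellml = c("name", "cmeta:id"),
         "id")
}

#' Match the nodes of two model documents
#'
#' Computes a partial one-to-one mapping between the element nodes of two
#' versions of a model. Matching priority: (1) equal value of the dialect's
#' identity attribute on equal-tag elements, unique in both documents;
#' (2) equal tag and equal `name` attribute among children of matched
#' parents; (3) equal tag and equal position among the remaining unmatched
#' same-tag siblings of matched parents.
#'
#' @param doc_a,doc_b `model_document` objects (see [read_model()]).
#' @param dialect Overrides the documents' dialect; one of `"sbml"`,
#'   `"cellml"`, `"generic"`.
#' @return A `node_mapping` object; its `pairs` component is a data frame
#'   of matched `uid_a`/`uid_b` node identifiers.
#' @export
match_trees <- function(doc_a, doc_b, dialect = NULL) {
  doc_a <- as_model_document(doc_a)
  doc_b <- as_model_document(doc_b)
  dialect <- normalize_dialect(dialect %||% doc_a$dialect)

  nodes_a <- tree_nodes(doc_a$tree)
  nodes_b <- tree_nodes(doc_b$tree)
  a2b <- new.env(parent = emptyenv())  # uid_a -> node_b
  b2a <- new.env(parent = emptyenv())
  matched_a <- function(n) !is.null(a2b[[as.character(n$uid)]])
  matched_b <- function(n) !is.null(b2a[[as.character(n$uid)]])
  set_match <- function(na, nb) {
    a2b[[as.character(na$uid)]] <- nb
    b2a[[as.character(nb$uid)]] <- na
  }

  # (1) global identity pass, attribute priority order
  for (idattr in dialect_id_attrs(dialect)) {
    key <- function(n) {
      v <- n$attrs[idattr]
      if (is.na(v)) NA_character_ else paste0(n$tag, "\r", unname(v))
    }
    ka <- vapply(nodes_a, function(n) if (matched_a(n)) NA_character_ else key(n), character(1))
    kb <- vapply(nodes_b, function(n) if (matched_b(n)) NA_character_ else key(n), character(1))
    ta <- table(ka[!is.na(ka)])
    tb <- table(kb[!is.na(kb)])
    uniq <- intersect(names(ta)[ta == 1L], names(tb)[tb == 1L])
    for (k in uniq) {
      set_match(nodes_a[[which(ka == k)[1]]], nodes_b[[which(kb == k)[1]]])
    }
  }

  # seed worklist: roots (if same tag) plus all identity-matched pairs in
  # document order of A
  if (!matched_a(doc_a$tree) && !matched_b(doc_b$tree) &&
      identical(doc_a$tree$tag, doc_b$tree$tag)) {
    set_match(doc_a$tree, doc_b$tree)
  }
  queue <- Filter(matched_a, nodes_a)
  seen <- new.env(parent = emptyenv())
  qi <- 1L
  while (qi <= length(queue)) {
    na <- queue[[qi]]; qi <- qi + 1L
    if (!is.null(seen[[as.character(na$uid)]])) next
    seen[[as.character(na$uid)]] <- TRUE
    nb <- a2b[[as.character(na$uid)]]

    # (2) children by (tag, name attribute), unique on both sides
    un_a <- Filter(Negate(matched_a), na$children)
    un_b <- Filter(Negate(matched_b), nb$children)
    nkey <- function(n) {
      v <- n$attrs["name"]
      if (is.na(v)) NA_character_ else paste0(n$tag, "\r", unname(v))
    }
    ka <- vapply(un_a, nkey, character(1))
    kb <- vapply(un_b, nkey, character(1))
    ta <- table(ka[!is.na(ka)]); tb <- table(kb[!is.na(kb)])
    for (k in intersect(names(ta)[ta == 1L], names(tb)[tb == 1L])) {
      set_match(un_a[[which(ka == k)[1]]], un_b[[which(kb == k)[1]]])
    }

    # (3) remaining children positionally, per tag
    un_a <- Filter(Negate(matched_a), na$children)
    un_b <- Filter(Negate(matched_b), nb$children)
    for (tg in unique(vapply(un_a, function(n) n$tag, character(1)))) {
      sa <- Filter(function(n) identical(n$tag, tg), un_a)
      sb <- Filter(function(n) identical(n$tag, tg), un_b)
      for (i in seq_len(min(length(sa), length(sb)))) set_match(sa[[i]], sb[[i]])
    }

    # recurse into matched children (including identity matches landing here)
    for (ch in na$children) {
      if (matched_a(ch)) queue[[length(queue) + 1L]] <- ch
    }
  }

  pairs <- do.call(rbind, lapply(nodes_a, function(n) {
    nb <- a2b[[as.character(n$uid)]]
    if (is.null(nb)) NULL else data.frame(uid_a = n$uid, uid_b = nb$uid)
  })) %||% data.frame(uid_a = integer(), uid_b = integer())

  structure(list(pairs = pairs, a2b = a2b, b2a = b2a,
                 doc_a = doc_a, doc_b = doc_b, dialect = dialect),
            class = "node_mapping")
}

#' @export
print.node_mapping <- function(x, ...) {
  cat(sprintf("<node_mapping> %d matched node pairs (dialect=%s)\n",
              nrow(x$pairs), x$dialect))
  invisible(x)
}

# longest strictly increasing subsequence; returns indices into x
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer())
  best <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  out <- integer()
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

new_op <- function(kind, entity_kind, address_a = NA_character_,
                   address_b = NA_character_, attribute = NA_character_,
                   old_value = NA_character_, new_value = NA_character_,
                   after_b = NA_character_, order_b = NA_integer_) {
  structure(list(op_id = NA_character_, kind = kind, entity_kind = entity_kind,
                 address_a = address_a, address_b = address_b,
                 attribute = attribute, old_value = old_value,
                 new_value = new_value, after_b = after_b, order_b = order_b,
                 triggered_by = character()),
            class = "change_op")
}

#' @export
print.change_op <- function(x, ...) {
  loc <- if (!is.na(x$address_a)) x$address_a else x$address_b
  extra <- if (!is.na(x$attribute)) paste0(" @", x$attribute) else ""
  val <- if (x$kind == "Update") sprintf(" '%s' -> '%s'", x$old_value, x$new_value)
         else if (!is.na(x$new_value)) sprintf(" '%s'", x$new_value)
         else if (!is.na(x$old_value)) sprintf(" '%s'", x$old_value)
         else ""
  trig <- if (length(x$triggered_by)) paste0(" <=", paste(x$triggered_by, collapse = ",")) else ""
  cat(sprintf("%s %s %s%s%s%s%s\n", x$op_id %||% "?", x$kind, x$entity_kind,
              paste0(" ", loc), extra, val, trig))
  invisible(x)
}

# position of node in B preorder; also predecessor-sibling address
b_order_index <- function(nodes_b) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(nodes_b)) idx[[as.character(nodes_b[[i]]$uid)]] <- i
  idx
}

preceding_sibling_address <- function(node) {
  p <- node$parent
  if (is.null(p)) return(NA_character_)
  pos <- which(vapply(p$children, identical, logical(1), y = node))
  if (pos == 1L) NA_character_ else node_address(p$children[[pos - 1L]])
}

#' Compute the delta between two model versions
#'
#' Produces the ordered set of Insertion/Deletion/Update/Move operations
#' that transforms `doc_a` into `doc_b` (the patch contract: applying the
#' delta to `doc_a` with [apply_delta()] yields a document canonically
#' equal to `doc_b`). Attribute-level differences on matched nodes are
#' emitted per attribute; text content differences per text node. Trigger
#' links between containment-dependent operations are populated via
#' [infer_triggers()].
#'
#' @param doc_a,doc_b `model_document` objects.
#' @param mapping Optional `node_mapping` from [match_trees()]; computed if
#'   missing.
#' @param dialect Overrides the documents' dialect.
#' @return A `model_delta` object.
#' @examples
#' a <- model_from_xml('<sbml xmlns="http://www.sbml.org/sbml/level2/version4">
#'   <model id="m"><listOfParameters>
#'     <parameter id="Km1" value="23.24"/>
#'   </listOfParameters></model></sbml>')
#' b <- model_from_xml(gsub("23.24", "23.42", model_to_xml(a), fixed = TRUE))
#' compute_delta(a, b)
#' @export
compute_delta <- function(doc_a, doc_b, mapping = NULL, dialect = NULL) {
  doc_a <- as_model_document(doc_a)
  doc_b <- as_model_document(doc_b)
  dialect <- normalize_dialect(dialect %||% doc_a$dialect)
  if (is.null(mapping)) mapping <- match_trees(doc_a, doc_b, dialect)
  if (anyDuplicated(mapping$pairs$uid_a) || anyDuplicated(mapping$pairs$uid_b)) {
    stop("inconsistent mapping: a node is matched more than once", call. = FALSE)
  }

  nodes_a <- tree_nodes(doc_a$tree)
  nodes_b <- tree_nodes(doc_b$tree)
  border <- b_order_index(nodes_b)
  a2b <- mapping$a2b
  b2a <- mapping$b2a
  bmatch <- function(n) a2b[[as.character(n$uid)]]
  amatch <- function(n) b2a[[as.character(n$uid)]]

  dels <- list(); upds <- list(); movs <- list(); inss <- list()
  push <- function(lst, op) { lst[[length(lst) + 1L]] <- op; lst }

  # deletions: unmatched nodes of A, their attributes and text
  for (na in nodes_a) {
    if (!is.null(bmatch(na))) next
    addr <- node_address(na)
    dels <- push(dels, new_op("Deletion", "XmlNode", address_a = addr))
    for (an in names(na$attrs) %||% character()) {
      dels <- push(dels, new_op("Deletion", "XmlAttribute", address_a = addr,
                                attribute = an, old_value = unname(na$attrs[[an]])))
    }
    if (nzchar(na$text)) {
      dels <- push(dels, new_op("Deletion", "XmlText", address_a = addr,
                                old_value = na$text))
    }
  }

  # updates on matched nodes: per-attribute and text differences
  for (na in nodes_a) {
    nb <- bmatch(na)
    if (is.null(nb)) next
    addr_a <- node_address(na); addr_b <- node_address(nb)
    ord_b <- border[[as.character(nb$uid)]]
    nm_a <- names(na$attrs) %||% character()
    nm_b <- names(nb$attrs) %||% character()
    for (an in nm_a) {
      va <- unname(na$attrs[[an]])
      if (an %in% nm_b) {
        vb <- unname(nb$attrs[[an]])
        if (!identical(va, vb)) {
          upds <- push(upds, new_op("Update", "XmlAttribute", address_a = addr_a,
                                    address_b = addr_b, attribute = an,
                                    old_value = va, new_value = vb))
        }
      } else {
        upds <- push(upds, new_op("Deletion", "XmlAttribute", address_a = addr_a,
                                  attribute = an, old_value = va))
      }
    }
    for (an in setdiff(nm_b, nm_a)) {
      inss <- push(inss, new_op("Insertion", "XmlAttribute", address_b = addr_b,
                                attribute = an, new_value = unname(nb$attrs[[an]]),
                                order_b = ord_b))
    }
    if (!identical(na$text, nb$text)) {
      if (nzchar(na$text) && nzchar(nb$text)) {
        upds <- push(upds, new_op("Update", "XmlText", address_a = addr_a,
                                  address_b = addr_b, old_value = na$text,
                                  new_value = nb$text))
      } else if (nzchar(na$text)) {
        upds <- push(upds, new_op("Deletion", "XmlText", address_a = addr_a,
                                  old_value = na$text))
      } else {
        inss <- push(inss, new_op("Insertion", "XmlText", address_b = addr_b,
                                  new_value = nb$text, order_b = ord_b))
      }
    }
  }

  # moves: re-parented matches, plus same-parent reorders off the longest
  # increasing subsequence of kept children
  reparented <- new.env(parent = emptyenv())
  for (na in nodes_a) {
    nb <- bmatch(na)
    if (is.null(nb)) next
    pa <- na$parent; pb <- nb$parent
    if (is.null(pa) || is.null(pb)) next
    pam <- bmatch(pa)
    if (is.null(pam) || !identical(pam, pb)) {
      reparented[[as.character(na$uid)]] <- TRUE
      movs <- push(movs, new_op("Move", "XmlNode", address_a = node_address(na),
                                address_b = node_address(nb),
                                after_b = preceding_sibling_address(nb),
                                order_b = border[[as.character(nb$uid)]]))
    }
  }
  for (na in nodes_a) {
    nb <- bmatch(na)
    if (is.null(nb)) next
    kept_a <- Filter(function(ch) {
      chb <- bmatch(ch)
      !is.null(chb) && identical(chb$parent, nb) &&
        is.null(reparented[[as.character(ch$uid)]])
    }, na$children)
    if (length(kept_a) < 2L) next
    posb <- vapply(kept_a, function(ch) {
      chb <- bmatch(ch)
      which(vapply(nb$children, identical, logical(1), y = chb))
    }, integer(1))
    keep <- lis_indices(posb)
    for (i in setdiff(seq_along(kept_a), keep)) {
      ch <- kept_a[[i]]; chb <- bmatch(ch)
      movs <- push(movs, new_op("Move", "XmlNode", address_a = node_address(ch),
                                address_b = node_address(chb),
                                after_b = preceding_sibling_address(chb),
                                order_b = border[[as.character(chb$uid)]]))
    }
  }

  # insertions: unmatched nodes of B, their attributes and text
  node_inss <- list()
  for (nb in nodes_b) {
    if (!is.null(amatch(nb))) next
    addr <- node_address(nb)
    ord_b <- border[[as.character(nb$uid)]]
    node_inss <- push(node_inss, new_op("Insertion", "XmlNode", address_b = addr,
                                        after_b = preceding_sibling_address(nb),
                                        order_b = ord_b))
    for (an in names(nb$attrs) %||% character()) {
      node_inss <- push(node_inss, new_op("Insertion", "XmlAttribute",
                                          address_b = addr, attribute = an,
                                          new_value = unname(nb$attrs[[an]]),
                                          order_b = ord_b))
    }
    if (nzchar(nb$text)) {
      node_inss <- push(node_inss, new_op("Insertion", "XmlText", address_b = addr,
                                          new_value = nb$text, order_b = ord_b))
    }
  }
  inss <- c(inss, node_inss)

  ops <- c(dels, upds, movs, inss)
  for (i in seq_along(ops)) ops[[i]]$op_id <- sprintf("op%d", i)
  delta <- structure(list(operations = ops, doc_a_ref = doc_a$ref,
                          doc_b_ref = doc_b$ref, dialect = dialect),
                     class = "model_delta")
  infer_triggers(delta)
}

#' One-call diff of two model versions
#'
#' Convenience wrapper: reads the documents if paths are given, matches the
#' trees and computes the delta.
#'
#' @param a,b `model_document` objects, XML strings, or file paths.
#' @param dialect See [read_model()].
#' @return A `model_delta`.
#' @export
diff_models <- function(a, b, dialect = NULL) {
  doc_a <- as_model_document(a)
  doc_b <- as_model_document(b)
  compute_delta(doc_a, doc_b, dialect = dialect)
}

#' @export
print.model_delta <- function(x, n = 10L, ...) {
  kinds <- vapply(x$operations, function(o) o$kind, character(1))
  cat(sprintf("<model_delta> %s -> %s (dialect=%s): %d operations\n",
              x$doc_a_ref, x$doc_b_ref, x$dialect, length(x$operations)))
  if (length(kinds)) {
    tab <- table(factor(kinds, levels = c("Insertion", "Deletion", "Update", "Move")))
    cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
    for (op in utils::head(x$operations, n)) { cat("  "); print(op) }
    if (length(x$operations) > n) cat(sprintf("  ... %d more\n", length(x$operations) - n))
  }
  invisible(x)
}

#' Number of operations in a delta
#' @param x A `model_delta`.
#' @export
length.model_delta <- function(x) length(x$operations)
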