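# Applying a delta to a document.
#
# Application order: attribute/text updates and deletions first (addresses
# in A coordinates, resolved against the pristine working tree), then node
# deletions and move-detachments deepest-and-last-sibling first, then node
# re-attachments and insertions in document order of B. Insert-phase
# operations place elements after the preceding sibling recorded in the
# delta (afterB), which is always already present when operations are
# applied in B document order.

#' Apply a delta to a model document (patch)
#'
#' Transforms `doc_a` into the version the delta was computed against. The
#' result is canonically equal (see [canonicalize()]) to the original
#' `doc_b` of [compute_delta()].
#'
#' @param doc_a The source `model_document`.
#' @param delta A `model_delta` computed from `doc_a`.
#' @return A new `model_document`.
#' @export
apply_delta <- function(doc_a, delta) {
  doc_a <- as_model_document(doc_a)
  stopifnot(inherits(delta, "model_delta"))
  vroot <- make_vroot(tree_copy(doc_a$tree))
  ops <- delta$operations

  needs_a <- vapply(ops, function(o) o$kind %in% c("Deletion", "Update", "Move"),
                    logical(1))
  resolved <- vector("list", length(ops))
  for (i in which(needs_a)) {
    op <- ops[[i]]
    node <- resolve_address(vroot, op$address_a)
    if (is.null(node)) {
      stop(sprintf("unresolvable address '%s' for operation %s",
                   op$address_a, op$op_id), call. = FALSE)
    }
    resolved[[i]] <- node
  }

  # conflict detection: two writes to the same slot
  slot <- vapply(seq_along(ops), function(i) {
    op <- ops[[i]]
    if (!needs_a[i]) return(NA_character_)
    paste(op$kind == "Move", op$address_a, op$entity_kind,
          op$attribute %||% NA_character_, sep = "\r")
  }, character(1))
  dup <- slot[!is.na(slot)][duplicated(slot[!is.na(slot)])]
  if (length(dup)) {
    bad <- ops[[which(slot %in% dup)[1]]]
    stop(sprintf("conflict: multiple operations write %s '%s'",
                 bad$entity_kind, bad$address_a), call. = FALSE)
  }

  # phase 1: updates and attribute/text deletions (non-structural)
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    node <- resolved[[i]]
    if (op$kind == "Update") {
      if (op$entity_kind == "XmlAttribute") {
        if (!(op$attribute %in% names(node$attrs))) {
          stop(sprintf("unresolvable address: attribute '%s' absent at '%s' (operation %s)",
                       op$attribute, op$address_a, op$op_id), call. = FALSE)
        }
        node$attrs[[op$attribute]] <- op$new_value
      } else if (op$entity_kind == "XmlText") {
        node$text <- normalize_ws(op$new_value)
      }
    } else if (op$kind == "Deletion" && op$entity_kind == "XmlAttribute") {
      node$attrs <- node$attrs[setdiff(names(node$attrs), op$attribute)]
    } else if (op$kind == "Deletion" && op$entity_kind == "XmlText") {
      node$text <- ""
    }
  }

  # phase 2: node deletions and move detachments, deepest/last first
  detach <- function(node) {
    p <- node$parent
    keep <- !vapply(p$children, identical, logical(1), y = node)
    p$children <- p$children[keep]
    node$parent <- NULL
  }
  struct_idx <- which(vapply(ops, function(o) {
    (o$kind == "Deletion" || o$kind == "Move") && o$entity_kind == "XmlNode"
  }, logical(1)))
  if (length(struct_idx)) {
    depth_key <- vapply(struct_idx, function(i) {
      st <- parse_address(ops[[i]]$address_a)
      paste(sprintf("%s[%06d]", st$tag, st$k), collapse = "/")
    }, character(1))
    struct_idx <- struct_idx[order(depth_key, method = "radix", decreasing = TRUE)]
    stash <- list()
    for (i in struct_idx) {
      node <- resolved[[i]]
      detach(node)
      if (ops[[i]]$kind == "Move") stash[[ops[[i]]$op_id]] <- node
    }
  } else stash <- list()

  # phase 3: insertions and move re-attachments in B document order
  ins_idx <- which(vapply(ops, function(o) {
    o$kind == "Insertion" || o$kind == "Move"
  }, logical(1)))
  if (length(ins_idx)) {
    ord <- vapply(ins_idx, function(i) ops[[i]]$order_b %||% NA_integer_, integer(1))
    tie <- vapply(ins_idx, function(i) ops[[i]]$entity_kind != "XmlNode", logical(1))
    ins_idx <- ins_idx[order(ord, tie)]
    for (i in ins_idx) {
      op <- ops[[i]]
      if (op$entity_kind == "XmlNode") {
        parent_addr <- address_parent(op$address_b)
        parent <- resolve_address(vroot, parent_addr)
        if (is.null(parent)) {
          stop(sprintf("unresolvable address '%s' for operation %s",
                       parent_addr, op$op_id), call. = FALSE)
        }
        node <- if (op$kind == "Move") {
          stash[[op$op_id]]
        } else {
          st <- parse_address(op$address_b)
          new_tnode(st$tag[nrow(st)])
        }
        pos <- 1L
        if (!is.na(op$after_b)) {
          pred <- resolve_address(vroot, op$after_b)
          if (is.null(pred)) {
            stop(sprintf("unresolvable address '%s' for operation %s",
                         op$after_b, op$op_id), call. = FALSE)
          }
          pos <- which(vapply(parent$children, identical, logical(1), y = pred)) + 1L
        }
        node$parent <- parent
        parent$children <- append(parent$children, list(node), after = pos - 1L)
      } else {
        node <- resolve_address(vroot, op$address_b)
        if (is.null(node)) {
          stop(sprintf("unresolvable address '%s' for operation %s",
                       op$address_b, op$op_id), call. = FALSE)
        }
        if (op$entity_kind == "XmlAttribute") {
          node$attrs[[op$attribute]] <- op$new_value
        } else {
          node$text <- normalize_ws(op$new_value)
        }
      }
    }
  }

  if (length(vroot$children) != 1L) {
    stop(sprintf("patch produced %d document elements", length(vroot$children)),
         call. = FALSE)
  }
  root <- vroot$children[[1]]
  root$parent <- NULL
  new_model_document(root, doc_a$dialect, paste0(delta$doc_b_ref, " (patched)"))
}
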