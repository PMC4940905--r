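# Internal element tree used by the diff engine.
#
# Each node is an environment with fields:
#   tag      - qualified element name as written ("parameter", "rdf:RDF")
#   attrs    - named character vector in document order; xmlns declarations
#              are kept as ordinary attributes of the declaring element
#   text     - whitespace-normalized concatenation of the element's direct
#              text/CDATA children ("" if none)
#   children - list of child element nodes
#   parent   - parent node environment or NULL for the document element
#   uid      - integer unique within the document
#
# Mixed-content interleaving (text between child elements) is not preserved:
# model formats (SBML, CellML, MathML) use element content almost
# exclusively, and whitespace-only text is serialization churn that must not
# surface as differences.

`%||%` <- function(a, b) if (is.null(a)) b else a

new_tnode <- function(tag, attrs = character(), text = "", parent = NULL, uid = NA_integer_) {
  n <- new.env(parent = emptyenv())
  n$tag <- tag
  n$attrs <- attrs
  n$text <- text
  n$children <- list()
  n$parent <- parent
  n$uid <- uid
  n
}

normalize_ws <- function(x) {
  x <- gsub("[ \t\r\n]+", " ", x)
  trimws(x)
}

# Convert an xml2 document/node into a tnode tree. Element and attribute
# names keep their as-written prefixes; elements in a default namespace are
# left unprefixed (xml2 labels default namespaces d1, d2, ... in its
# namespace map, which we undo by consulting the in-scope default binding).
xml_to_tree <- function(x) {
  root <- xml2::xml_root(x)
  nsmap <- tryCatch(xml2::xml_ns(x), error = function(e) character())
  counter <- new.env(parent = emptyenv())
  counter$uid <- 0L

  build <- function(node, parent, default_uri, declared_prefixes) {
    attrs <- xml2::xml_attrs(node, ns = nsmap)
    if (is.null(attrs)) attrs <- character()
    # update namespace scope from this element's declarations
    nm <- names(attrs)
    if (length(nm)) {
      if ("xmlns" %in% nm) default_uri <- unname(attrs[["xmlns"]])
      pfx_decl <- sub("^xmlns:", "", nm[startsWith(nm, "xmlns:")])
      declared_prefixes <- union(declared_prefixes, pfx_decl)
    }
    name <- xml2::xml_name(node, ns = nsmap)
    if (grepl(":", name, fixed = TRUE)) {
      pfx <- sub(":.*$", "", name)
      # xml2 invents a prefix for default-namespace elements; strip it when
      # the prefix was never declared literally and its URI is the in-scope
      # default namespace
      if (!(pfx %in% declared_prefixes) &&
          !is.na(default_uri) && identical(unname(nsmap[pfx]), default_uri)) {
        name <- sub("^[^:]+:", "", name)
      }
    }
    counter$uid <- counter$uid + 1L
    tn <- new_tnode(name, attrs, "", parent, counter$uid)
    contents <- xml2::xml_contents(node)
    texts <- character()
    kids <- list()
    for (i in seq_along(contents)) {
      child <- contents[[i]]
      type <- xml2::xml_type(child)
      if (type == "element") {
        kids[[length(kids) + 1L]] <- build(child, tn, default_uri, declared_prefixes)
      } else if (type %in% c("text", "cdata")) {
        texts <- c(texts, xml2::xml_text(child))
      }
    }
    tn$children <- kids
    tn$text <- normalize_ws(paste(texts, collapse = " "))
    tn
  }
  build(root, NULL, NA_character_, character())
}

tree_copy <- function(node, parent = NULL) {
  n <- new_tnode(node$tag, node$attrs, node$text, parent, node$uid)
  n$children <- lapply(node$children, tree_copy, parent = n)
  n
}

walk_tree <- function(node, fun) {
  fun(node)
  for (ch in node$children) walk_tree(ch, fun)
  invisible(NULL)
}

tree_nodes <- function(root) {
  out <- list()
  walk_tree(root, function(n) out[[length(out) + 1L]] <<- n)
  out
}

# -- addressing ----------------------------------------------------------

# Address of a node: "/tag[k]/tag[k]/..." where k is the 1-based index of
# the node among same-tag siblings.
node_address <- function(node) {
  steps <- character()
  while (!is.null(node)) {
    p <- node$parent
    if (is.null(p)) {
      steps <- c(sprintf("%s[1]", node$tag), steps)
    } else {
      same <- Filter(function(s) identical(s$tag, node$tag), p$children)
      k <- which(vapply(same, identical, logical(1), y = node))
      steps <- c(sprintf("%s[%d]", node$tag, k), steps)
    }
    node <- p
  }
  paste0("/", paste(steps, collapse = "/"))
}

parse_address <- function(path) {
  steps <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  m <- regmatches(steps, regexec("^(.*)\\[([0-9]+)\\]$", steps))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop(sprintf("malformed address step '%s' in '%s'", steps[bad][1], path), call. = FALSE)
  data.frame(
    tag = vapply(m, `[[`, character(1), 2L),
    k = as.integer(vapply(m, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

address_parent <- function(path) {
  sub("/[^/]+$", "", path)
}

address_tags <- function(path) parse_address(path)$tag

# Resolve an address against a virtual root holding the document element(s)
# as children. Returns the node or NULL.
resolve_address <- function(vroot, path) {
  if (!nzchar(path)) return(vroot)
  steps <- parse_address(path)
  cur <- vroot
  for (i in seq_len(nrow(steps))) {
    same <- Filter(function(s) identical(s$tag, steps$tag[i]), cur$children)
    if (steps$k[i] > length(same)) return(NULL)
    cur <- same[[steps$k[i]]]
  }
  cur
}

make_vroot <- function(root) {
  v <- new_tnode("#document")
  root2 <- root
  root2$parent <- v
  v$children <- list(root2)
  v
}

# -- serialization -------------------------------------------------------

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  x <- xml_escape_text(x)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

serialize_node <- function(node, sort_attrs = FALSE, indent = NA_integer_) {
  attrs <- node$attrs
  if (sort_attrs && length(attrs)) attrs <- attrs[order(names(attrs), method = "radix")]
  astr <- if (length(attrs)) {
    paste0(" ", paste(sprintf("%s=\"%s\"", names(attrs), xml_escape_attr(unname(attrs))),
                      collapse = " "))
  } else ""
  pad <- if (is.na(indent)) "" else strrep("  ", indent)
  nl <- if (is.na(indent)) "" else "\n"
  if (!nzchar(node$text) && length(node$children) == 0L) {
    return(sprintf("%s<%s%s/>%s", pad, node$tag, astr, nl))
  }
  inner_indent <- if (is.na(indent)) NA_integer_ else indent + 1L
  kids <- vapply(node$children, serialize_node, character(1),
                 sort_attrs = sort_attrs, indent = inner_indent)
  body <- paste0(xml_escape_text(node$text), paste(kids, collapse = ""))
  if (!is.na(indent) && length(node$children)) {
    body <- paste0(xml_escape_text(node$text), "\n", paste(kids, collapse = ""), pad)
  }
  sprintf("%s<%s%s>%s</%s>%s", pad, node$tag, astr, body, node$tag, nl)
}

tree_to_xml <- function(root, pretty = TRUE) {
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
         serialize_node(root, sort_attrs = FALSE, indent = if (pretty) 0L else NA_integer_))
}

# -- canonical form ------------------------------------------------------

# Deterministic serialization defining document equality: attributes sorted
# by name, text whitespace-normalized (done at parse), and namespace
# prefixes renamed n1, n2, ... in order of first declaration (ordered by
# namespace URI within an element), so that two documents differing only in
# prefix spelling canonicalize identically. Default namespaces stay default.
canonicalize_tree <- function(root) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L

  canon <- function(node, scope) {
    attrs <- node$attrs
    nm <- names(attrs) %||% character()
    decl_idx <- which(nm == "xmlns" | startsWith(nm, "xmlns:"))
    if (length(decl_idx)) {
      decls <- attrs[decl_idx]
      # assign canonical prefixes ordered by URI (prefix-name independent)
      decls <- decls[order(unname(decls), names(decls), method = "radix")]
      for (j in seq_along(decls)) {
        dn <- names(decls)[j]
        if (dn == "xmlns") {
          scope[["{default}"]] <- ""
        } else {
          counter$n <- counter$n + 1L
          scope[[sub("^xmlns:", "", dn)]] <- sprintf("n%d", counter$n)
        }
      }
    }
    rename <- function(qname) {
      if (!grepl(":", qname, fixed = TRUE)) return(qname)
      pfx <- sub(":.*$", "", qname)
      local <- sub("^[^:]+:", "", qname)
      cp <- scope[[pfx]]
      if (is.null(cp)) qname else if (nzchar(cp)) paste0(cp, ":", local) else local
    }
    new_attrs <- attrs
    if (length(nm)) {
      new_nm <- nm
      for (i in seq_along(nm)) {
        if (nm[i] == "xmlns") next
        if (startsWith(nm[i], "xmlns:")) {
          new_nm[i] <- paste0("xmlns:", scope[[sub("^xmlns:", "", nm[i])]])
        } else {
          new_nm[i] <- rename(nm[i])
        }
      }
      names(new_attrs) <- new_nm
    }
    cn <- new_tnode(rename(node$tag), new_attrs, node$text)
    cn$children <- lapply(node$children, canon, scope = scope)
    cn
  }

  # scope as plain list copied down the recursion
  canon(root, list())
}

#' Canonical serialization of a model document
#'
#' Produces a deterministic single-string serialization in which attribute
#' order, insignificant whitespace and namespace prefix spelling do not
#' matter: two documents are considered equal exactly when their canonical
#' forms are byte-identical. This relation defines the patch contract
#' (`apply_delta(a, compute_delta(a, b))` equals `b` canonically).
#'
#' @param doc A `model_document` (see [read_model()]), an `xml_document`, or
#'   a length-1 character string of XML.
#' @return A single character string.
#' @examples
#' a <- model_from_xml('<m b="2" a="1"/>')
#' b <- model_from_xml('<m a="1"  b="2"></m>')
#' identical(canonicalize(a), canonicalize(b))
#' @export
canonicalize <- function(doc) {
  tree <- as_model_document(doc)$tree
  serialize_node(canonicalize_tree(tree), sort_attrs = TRUE, indent = NA_integer_)
}
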