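# Minimal Turtle (W3C TTL) reader/writer covering the subset this package
# emits and the common constructs of hand-written vocabulary files:
# @prefix/@base directives, IRIs, prefixed names, the 'a' keyword, string
# literals with escapes and optional datatype/language tags, and
# ';'/',' predicate-object list punctuation. Blank nodes and collections
# are not supported (the package never emits them).

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  out <- character(1)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  buf <- character()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && i < length(chars)) {
      nxt <- chars[i + 1L]
      buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                           "\"" = "\"", "\\" = "\\", nxt))
      i <- i + 2L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  paste(buf, collapse = "")
}

ttl_literal <- function(x) sprintf("\"%s\"", ttl_escape(x))

TTL_TOKEN_RE <- paste0(
  "@prefix|@base|",
  "<[^>]*>|",
  "\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^[^ \t\r\n;,.]+|@[A-Za-z][A-Za-z0-9-]*)?|",
  "[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]*|",
  ":[A-Za-z0-9_.%-]*|",
  "\\ba\\b|",
  "[;,.]"
)

ttl_tokenize <- function(text) {
  # strip comments: '#' to end of line when outside quotes and IRIs
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- vapply(lines, function(ln) {
    chars <- strsplit(ln, "", fixed = TRUE)[[1]]
    inq <- FALSE; iniri <- FALSE; esc <- FALSE
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (esc) { esc <- FALSE; next }
      if (inq) {
        if (ch == "\\") esc <- TRUE else if (ch == "\"") inq <- FALSE
      } else if (iniri) {
        if (ch == ">") iniri <- FALSE
      } else if (ch == "\"") inq <- TRUE
      else if (ch == "<") iniri <- TRUE
      else if (ch == "#") return(substr(ln, 1L, i - 1L))
    }
    ln
  }, character(1), USE.NAMES = FALSE)
  text <- paste(lines, collapse = "\n")
  m <- gregexpr(TTL_TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(token = character(), pos = integer()))
  data.frame(token = regmatches(text, list(m))[[1]], pos = as.integer(m),
             stringsAsFactors = FALSE)
}

ttl_error <- function(text, pos, msg) {
  prefix <- substr(text, 1L, pos)
  line <- length(strsplit(prefix, "\n", fixed = TRUE)[[1]])
  col <- pos - max(c(0L, gregexpr("\n", prefix, fixed = TRUE)[[1]]))
  stop(sprintf("Turtle parse error at line %d, column %d: %s", line, col, msg),
       call. = FALSE)
}

# Parses Turtle text into prefixes and a triple table. Objects that are
# literals carry is_literal = TRUE and the unescaped string value;
# IRI-valued terms are fully expanded (relative IRIs kept verbatim).
parse_turtle <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- ttl_tokenize(text)
  prefixes <- character()
  base <- ""
  triples <- list()
  i <- 1L
  n <- nrow(toks)

  expand <- function(tok, pos) {
    if (startsWith(tok, "<")) {
      iri <- substr(tok, 2L, nchar(tok) - 1L)
      if (nzchar(base) && !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri)) {
        iri <- paste0(base, iri)
      }
      return(list(value = iri, literal = FALSE))
    }
    if (startsWith(tok, "\"")) {
      lit <- sub("(\\^\\^[^ ]*|@[A-Za-z][A-Za-z0-9-]*)$", "", tok)
      return(list(value = ttl_unescape(substr(lit, 2L, nchar(lit) - 1L)),
                  literal = TRUE))
    }
    if (tok == "a") return(list(value = paste0(RDF_NS, "type"), literal = FALSE))
    cpos <- regexpr(":", tok, fixed = TRUE)
    pfx <- substr(tok, 1L, cpos - 1L)
    local <- substr(tok, cpos + 1L, nchar(tok))
    hit <- match(pfx, names(prefixes))
    if (is.na(hit)) {
      ttl_error(text, pos, sprintf("undeclared prefix '%s:'", pfx))
    }
    list(value = paste0(unname(prefixes[hit]), local), literal = FALSE)
  }
  peek <- function() if (i <= n) toks$token[i] else NA_character_
  take <- function() {
    if (i > n) ttl_error(text, nchar(text), "unexpected end of input")
    tok <- toks[i, ]; i <<- i + 1L; tok
  }

  while (i <= n) {
    tok <- take()
    if (tok$token == "@prefix") {
      pn <- take(); iri <- take(); dot <- take()
      if (!grepl(":$", pn$token) && !grepl(":", pn$token)) {
        ttl_error(text, pn$pos, "expected prefix name in @prefix")
      }
      if (!startsWith(iri$token, "<")) ttl_error(text, iri$pos, "expected IRI in @prefix")
      if (dot$token != ".") ttl_error(text, dot$pos, "expected '.' after @prefix")
      prefixes[sub(":.*$", "", pn$token)] <- substr(iri$token, 2L, nchar(iri$token) - 1L)
      next
    }
    if (tok$token == "@base") {
      iri <- take(); dot <- take()
      if (!startsWith(iri$token, "<")) ttl_error(text, iri$pos, "expected IRI in @base")
      if (dot$token != ".") ttl_error(text, dot$pos, "expected '.' after @base")
      base <- substr(iri$token, 2L, nchar(iri$token) - 1L)
      next
    }
    subj <- expand(tok$token, tok$pos)
    if (subj$literal) ttl_error(text, tok$pos, "literal cannot be a subject")
    repeat {
      ptok <- take()
      pred <- expand(ptok$token, ptok$pos)
      if (pred$literal) ttl_error(text, ptok$pos, "literal cannot be a predicate")
      repeat {
        otok <- take()
        obj <- expand(otok$token, otok$pos)
        triples[[length(triples) + 1L]] <- data.frame(
          s = subj$value, p = pred$value, o = obj$value,
          o_literal = obj$literal, stringsAsFactors = FALSE)
        sep <- take()
        if (sep$token == ",") next
        if (sep$token %in% c(";", ".")) break
        ttl_error(text, sep$pos, sprintf("expected ',', ';' or '.', got '%s'", sep$token))
      }
      if (sep$token == ".") break
      # ';' may be followed directly by '.', ending the subject
      if (identical(peek(), ".")) { take(); break }
    }
  }
  list(
    prefixes = prefixes,
    triples = if (length(triples)) do.call(rbind, triples)
              else data.frame(s = character(), p = character(), o = character(),
                              o_literal = logical(), stringsAsFactors = FALSE)
  )
}
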