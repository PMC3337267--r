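# Minimal RDF triple extraction for ontology documents.
#
# R has no maintained triple-store binding in this stack, so we extract the
# asserted triples we need (class declarations, labels, taxonomy edges,
# imports) directly: RDF/XML through xml2, Turtle through a small scanner.
# Triples are returned as a data frame with columns
#   subject, predicate, object, is_literal, lang
# Blank nodes are encoded as "_:b<N>" identifiers local to one parse.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"

rdf_iri  <- function(x) paste0(RDF_NS, x)
rdfs_iri <- function(x) paste0(RDFS_NS, x)
owl_iri  <- function(x) paste0(OWL_NS, x)

empty_triples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), is_literal = logical(),
             lang = character(), stringsAsFactors = FALSE)
}

triple_row <- function(s, p, o, is_literal = FALSE, lang = "") {
  data.frame(subject = s, predicate = p, object = o,
             is_literal = is_literal, lang = lang, stringsAsFactors = FALSE)
}

is_absolute_iri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) & !grepl("^_:", x)
}

#' Read RDF triples from an ontology document
#'
#' Auto-detects RDF/XML (`.owl`, `.rdf`, `.xml`) versus Turtle (`.ttl`) by
#' file extension, falling back to content sniffing (a leading `<` that is
#' not a Turtle IRI suggests XML).
#'
#' @param path Path to the document.
#' @param format One of `"auto"`, `"rdfxml"`, `"turtle"`.
#' @return A data frame of triples with columns `subject`, `predicate`,
#'   `object`, `is_literal`, `lang`.
#' @keywords internal
read_rdf_triples <- function(path, format = c("auto", "rdfxml", "turtle")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("ttl", "n3", "nt")) "turtle"
      else if (ext %in% c("owl", "rdf", "xml")) "rdfxml"
      else {
        head_txt <- readChar(path, nchars = min(file.size(path), 2048L),
                             useBytes = TRUE)
        if (grepl("^\\s*<\\?xml|^\\s*<rdf:RDF|^\\s*<!DOCTYPE", head_txt)) {
          "rdfxml"
        } else "turtle"
      }
  }
  switch(format,
         rdfxml = parse_rdfxml_triples(path),
         turtle = parse_turtle_triples(path))
}

# ---- RDF/XML -----------------------------------------------------------

expand_qname <- function(qname, ns_map) {
  parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(qname)
  prefix <- parts[1]
  local <- paste(parts[-1], collapse = ":")
  if (prefix %in% names(ns_map)) paste0(ns_map[[prefix]], local) else qname
}

parse_rdfxml_triples <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("failed to parse RDF/XML document '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  ns_map <- xml2::xml_ns(doc)
  state <- new.env(parent = emptyenv())
  state$counter <- 0L
  state$rows <- list()
  state$base <- xml2::xml_attr(doc, "base", default = "")

  attr_get <- function(attrs, name) {
    if (name %in% names(attrs)) attrs[[name]] else NULL
  }
  emit <- function(s, p, o, is_literal = FALSE, lang = "") {
    state$rows[[length(state$rows) + 1L]] <-
      list(s = s, p = p, o = o, lit = is_literal, lang = lang)
  }
  new_bnode <- function() {
    state$counter <- state$counter + 1L
    paste0("_:b", state$counter)
  }
  resolve_about <- function(x) {
    if (is_absolute_iri(x) || state$base == "") x else {
      if (startsWith(x, "#")) paste0(sub("#.*$", "", state$base), x)
      else paste0(state$base, x)
    }
  }

  node_subject <- function(el) {
    attrs <- xml2::xml_attrs(el, ns_map)
    if (!is.null(attr_get(attrs, "rdf:about"))) {
      return(resolve_about(attrs[["rdf:about"]]))
    }
    if (!is.null(attr_get(attrs, "rdf:ID"))) {
      return(paste0(sub("#.*$", "", state$base), "#", attrs[["rdf:ID"]]))
    }
    if (!is.null(attr_get(attrs, "rdf:nodeID"))) {
      return(paste0("_:", attrs[["rdf:nodeID"]]))
    }
    new_bnode()
  }

  # parse a node element, emitting its triples; returns the subject term
  parse_node <- function(el) {
    subj <- node_subject(el)
    tag <- expand_qname(xml2::xml_name(el, ns_map), ns_map)
    if (tag != rdf_iri("Description")) emit(subj, rdf_iri("type"), tag)
    attrs <- xml2::xml_attrs(el, ns_map)
    syntactic <- c("rdf:about", "rdf:ID", "rdf:nodeID", "xml:base", "xml:lang")
    for (an in setdiff(names(attrs), syntactic)) {
      if (startsWith(an, "xmlns")) next
      emit(subj, expand_qname(an, ns_map), attrs[[an]], is_literal = TRUE)
    }
    for (prop in xml2::xml_children(el)) parse_property(subj, prop)
    subj
  }

  parse_property <- function(subj, prop) {
    pred <- expand_qname(xml2::xml_name(prop, ns_map), ns_map)
    attrs <- xml2::xml_attrs(prop, ns_map)
    if (!is.null(attr_get(attrs, "rdf:resource"))) {
      emit(subj, pred, resolve_about(attrs[["rdf:resource"]]))
      return(invisible())
    }
    if (!is.null(attr_get(attrs, "rdf:nodeID"))) {
      emit(subj, pred, paste0("_:", attrs[["rdf:nodeID"]]))
      return(invisible())
    }
    kids <- xml2::xml_children(prop)
    ptype <- attr_get(attrs, "rdf:parseType")
    if (!is.null(ptype) && identical(ptype, "Resource")) {
      bn <- new_bnode()
      emit(subj, pred, bn)
      for (k in kids) parse_property(bn, k)
      return(invisible())
    }
    if (length(kids) > 0L) {
      for (k in kids) emit(subj, pred, parse_node(k))
      return(invisible())
    }
    lang <- attr_get(attrs, "xml:lang")
    emit(subj, pred, xml2::xml_text(prop),
         is_literal = TRUE, lang = if (is.null(lang)) "" else lang)
  }

  for (el in xml2::xml_children(doc)) parse_node(el)
  rows <- state$rows
  if (length(rows) == 0L) return(empty_triples())
  data.frame(
    subject = vapply(rows, `[[`, "", "s"),
    predicate = vapply(rows, `[[`, "", "p"),
    object = vapply(rows, `[[`, "", "o"),
    is_literal = vapply(rows, `[[`, NA, "lit"),
    lang = vapply(rows, `[[`, "", "lang"),
    stringsAsFactors = FALSE
  )
}

# ---- Turtle ------------------------------------------------------------

# Tokenizer: handles IRIs, prefixed names, blank nodes, string literals
# (short form, with escapes), language tags, datatype markers, the 'a'
# keyword, numbers/booleans and structural punctuation. Comments run from
# an unquoted '#' to end of line.
tokenize_turtle <- function(text) {
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  push <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\r", "\n")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L; next }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("unterminated IRI in Turtle document", call. = FALSE)
      push("iri", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L; next
    }
    if (ch == '"') {
      j <- i + 1L
      out <- character()
      while (j <= n && chars[j] != '"') {
        if (chars[j] == "\\" && j < n) {
          esc <- chars[j + 1L]
          out <- c(out, switch(esc, n = "\n", t = "\t", r = "\r",
                               '"' = '"', "\\" = "\\", esc))
          j <- j + 2L
        } else {
          out <- c(out, chars[j]); j <- j + 1L
        }
      }
      if (j > n) stop("unterminated string literal in Turtle document",
                      call. = FALSE)
      push("string", paste(out, collapse = ""))
      i <- j + 1L; next
    }
    if (ch == "@") {
      j <- i + 1L
      while (j <= n && grepl("[A-Za-z0-9-]", chars[j])) j <- j + 1L
      word <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (word %in% c("prefix", "base")) push("directive", word)
      else push("langtag", word)
      i <- j; next
    }
    if (ch == "^" && i < n && chars[i + 1L] == "^") {
      push("datatype_marker", "^^"); i <- i + 2L; next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push(ch, ch); i <- i + 1L; next
    }
    # pname / blank node / keyword / number
    j <- i
    while (j <= n && !grepl('[ \t\r\n<>"\\^;,\\[\\]()]', chars[j], perl = TRUE)) {
      # '.' terminates a statement unless it is interior to the token
      if (chars[j] == "." &&
          (j == n || grepl('[ \t\r\n]', chars[min(j + 1L, n)]))) break
      j <- j + 1L
    }
    word <- paste(chars[i:(j - 1L)], collapse = "")
    if (word == "") stop("tokenizer stall in Turtle document", call. = FALSE)
    if (word == "a") push("keyword_a", "a")
    else if (startsWith(word, "_:")) push("bnode", word)
    else if (grepl(":", word, fixed = TRUE)) push("pname", word)
    else push("plain", word)
    i <- j
  }
  tokens
}

parse_turtle_triples <- function(path) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  toks <- tokenize_turtle(text)
  prefixes <- list()
  base <- ""
  rows <- list()
  bcount <- 0L
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() {
    t <- toks[[pos]]; pos <<- pos + 1L; t
  }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) {
      stop("Turtle parse error near token ", pos, ": expected ", type,
           call. = FALSE)
    }
    advance()
  }
  emit <- function(s, p, o, lit = FALSE, lang = "") {
    rows[[length(rows) + 1L]] <<- list(s = s, p = p, o = o, lit = lit,
                                       lang = lang)
  }
  new_bnode <- function() {
    bcount <<- bcount + 1L
    paste0("_:tb", bcount)
  }
  expand_pname <- function(pn) {
    parts <- regmatches(pn, regexpr(":", pn), invert = TRUE)[[1]]
    prefix <- parts[1]; local <- parts[2]
    if (!prefix %in% names(prefixes) && prefix != "") {
      stop("undeclared Turtle prefix '", prefix, ":'", call. = FALSE)
    }
    base_iri <- if (prefix == "") {
      if (is.null(prefixes[[":"]])) "" else prefixes[[":"]]
    } else prefixes[[prefix]]
    paste0(base_iri, local)
  }
  resolve <- function(iri) {
    if (is_absolute_iri(iri) || base == "") iri else paste0(base, iri)
  }

  parse_term <- function() {
    t <- advance()
    switch(t$type,
      iri = list(term = resolve(t$value), lit = FALSE, lang = ""),
      pname = list(term = expand_pname(t$value), lit = FALSE, lang = ""),
      bnode = list(term = t$value, lit = FALSE, lang = ""),
      keyword_a = list(term = rdf_iri("type"), lit = FALSE, lang = ""),
      string = {
        lang <- ""
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == "langtag") {
          lang <- advance()$value
        } else if (!is.null(nxt) && nxt$type == "datatype_marker") {
          advance(); advance()  # discard datatype IRI
        }
        list(term = t$value, lit = TRUE, lang = lang)
      },
      "[" = {
        bn <- new_bnode()
        if (!is.null(peek()) && peek()$type != "]") parse_predicate_list(bn)
        expect("]")
        list(term = bn, lit = FALSE, lang = "")
      },
      "(" = {
        while (!is.null(peek()) && peek()$type != ")") parse_term()
        expect(")")
        list(term = new_bnode(), lit = FALSE, lang = "")
      },
      plain = list(term = t$value, lit = TRUE, lang = ""),
      stop("Turtle parse error: unexpected token '", t$value, "'",
           call. = FALSE)
    )
  }

  parse_predicate_list <- function(subj) {
    repeat {
      pred <- parse_term()
      if (pred$lit) stop("Turtle parse error: literal in predicate position",
                         call. = FALSE)
      repeat {
        obj <- parse_term()
        emit(subj, pred$term, obj$term, obj$lit, obj$lang)
        if (!is.null(peek()) && peek()$type == ",") advance() else break
      }
      if (!is.null(peek()) && peek()$type == ";") {
        advance()
        if (!is.null(peek()) && peek()$type %in% c(".", "]")) break
      } else break
    }
  }

  while (!is.null(peek())) {
    t <- peek()
    if (t$type == "directive") {
      advance()
      if (t$value == "prefix") {
        pn <- expect("pname")$value
        prefix <- sub(":.*$", "", pn)
        iri <- expect("iri")$value
        prefixes[[if (prefix == "") ":" else prefix]] <- iri
        expect(".")
      } else {
        base <- expect("iri")$value
        expect(".")
      }
      next
    }
    subj <- parse_term()
    if (subj$lit) stop("Turtle parse error: literal in subject position",
                       call. = FALSE)
    parse_predicate_list(subj$term)
    expect(".")
  }

  if (length(rows) == 0L) return(empty_triples())
  data.frame(
    subject = vapply(rows, `[[`, "", "s"),
    predicate = vapply(rows, `[[`, "", "p"),
    object = vapply(rows, `[[`, "", "o"),
    is_literal = vapply(rows, `[[`, NA, "lit"),
    lang = vapply(rows, `[[`, "", "lang"),
    stringsAsFactors = FALSE
  )
}
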