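## Minimal RDF layer: a Turtle subset reader producing a triple frame, and
## canonical Turtle / RDF/XML writers. The subset covers what the package
## itself emits plus ordinary ontology documents: @prefix directives,
## predicate-object lists with ';' and ',', 'a', typed literals, blank-node
## property lists and RDF collections.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

rdf_uri  <- function(x) paste0(RDF_NS, x)
rdfs_uri <- function(x) paste0(RDFS_NS, x)
owl_uri  <- function(x) paste0(OWL_NS, x)
xsd_uri  <- function(x) paste0(XSD_NS, x)

triple_frame <- function() {
  data.frame(s = character(), p = character(), o = character(),
             o_kind = character(), o_datatype = character(),
             stringsAsFactors = FALSE)
}

## ---- tokenizer -------------------------------------------------------------

ttl_tokenize <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  i <- 1L
  toks <- list()
  push <- function(type, value = "") toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\r", "\n")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L; next }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("turtle parse error: unterminated IRI")
      push("iri", paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L; buf <- character(0)
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\\" && j < n) { buf <- c(buf, chars[j + 1L]); j <- j + 2L }
        else { buf <- c(buf, chars[j]); j <- j + 1L }
      }
      if (j > n) stop("turtle parse error: unterminated string literal")
      push("string", paste0(buf, collapse = ""))
      i <- j + 1L; next
    }
    if (ch == "^" && i < n && chars[i + 1L] == "^") { push("dt"); i <- i + 2L; next }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      ## '.' inside a qname-ish token is handled below; here '.' is a terminator
      push(ch); i <- i + 1L; next
    }
    ## bare word: prefixed name, 'a', '@prefix', numbers
    j <- i
    while (j <= n && !chars[j] %in% c(" ", "\t", "\r", "\n", ";", ",", "[", "]",
                                      "(", ")", "\"", "<", "#")) j <- j + 1L
    word <- paste0(chars[i:(j - 1L)], collapse = "")
    ## a trailing '.' terminates the statement unless part of a decimal number
    if (grepl("\\.$", word) && !grepl("^[+-]?[0-9.]+$", word)) {
      word <- sub("\\.$", "", word)
      if (nzchar(word)) push_word(word, push)
      push(".")
    } else push_word(word, push)
    i <- j
  }
  toks
}

push_word <- function(word, push) {
  if (word == "a") push("a")
  else if (word %in% c("@prefix", "@base", "PREFIX", "BASE")) push("directive", word)
  else if (grepl("^[A-Za-z0-9_.\\-]*:[A-Za-z0-9_.\\-]*$", word)) push("pname", word)
  else if (grepl("^[+-]?[0-9]+$", word)) push("number", word)
  else if (grepl("^[+-]?[0-9]*\\.[0-9]+$", word)) push("dec_number", word)
  else if (word %in% c("true", "false")) push("bool", word)
  else stop("turtle parse error: unexpected token '", word, "'")
}

## ---- parser ----------------------------------------------------------------

#' Parse a Turtle document into a triple data frame
#'
#' Supports the subset the package itself writes (see the package
#' serializers) plus plain ontology documents. Returns a data frame with
#' columns `s`, `p`, `o`, `o_kind` ("uri", "literal" or "blank") and
#' `o_datatype` (xsd datatype URI for literals), with attribute `prefixes`.
#'
#' @param text Turtle document text.
#' @return triple data frame.
#' @export
parse_turtle <- function(text) {
  toks <- ttl_tokenize(text)
  pos <- 1L
  prefixes <- character(0)
  rows <- list()
  bn <- 0L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else list(type = "eof")
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- advance()
    if (t$type != type) stop("turtle parse error: expected ", type, " got ", t$type)
    t
  }
  new_blank <- function() { bn <<- bn + 1L; paste0("_:b", bn) }
  resolve_pname <- function(p) {
    parts <- strsplit(p, ":", fixed = TRUE)[[1]]
    pre <- if (length(parts) >= 1L) parts[1] else ""
    loc <- if (length(parts) >= 2L) parts[2] else ""
    base <- prefixes[pre]
    if (is.na(base)) stop("turtle parse error: undeclared prefix '", pre, ":'")
    paste0(unname(base), loc)
  }
  emit <- function(s, p, o, kind, dt = NA_character_)
    rows[[length(rows) + 1L]] <<- list(s = s, p = p, o = o, o_kind = kind,
                                       o_datatype = dt)
  parse_object <- function() {
    t <- peek()
    if (t$type == "iri") { advance(); list(o = t$value, kind = "uri") }
    else if (t$type == "pname") { advance(); list(o = resolve_pname(t$value), kind = "uri") }
    else if (t$type == "string") {
      advance()
      dt <- xsd_uri("string")
      if (peek()$type == "dt") {
        advance()
        dtt <- advance()
        dt <- if (dtt$type == "iri") dtt$value
              else if (dtt$type == "pname") resolve_pname(dtt$value)
              else stop("turtle parse error: bad datatype")
      }
      list(o = t$value, kind = "literal", dt = dt)
    }
    else if (t$type == "number") { advance(); list(o = t$value, kind = "literal", dt = xsd_uri("integer")) }
    else if (t$type == "dec_number") { advance(); list(o = t$value, kind = "literal", dt = xsd_uri("decimal")) }
    else if (t$type == "bool") { advance(); list(o = t$value, kind = "literal", dt = xsd_uri("boolean")) }
    else if (t$type == "[") {
      advance()
      id <- new_blank()
      if (peek()$type != "]") parse_pol(id)
      expect("]")
      list(o = id, kind = "blank")
    }
    else if (t$type == "(") {
      advance()
      items <- list()
      while (peek()$type != ")") items[[length(items) + 1L]] <- parse_object()
      expect(")")
      if (length(items) == 0L) return(list(o = rdf_uri("nil"), kind = "uri"))
      head_id <- new_blank(); cur <- head_id
      for (k in seq_along(items)) {
        it <- items[[k]]
        emit(cur, rdf_uri("first"), it$o, it$kind, it$dt %||% NA_character_)
        nxt <- if (k < length(items)) new_blank() else rdf_uri("nil")
        emit(cur, rdf_uri("rest"), nxt, if (k < length(items)) "blank" else "uri")
        cur <- nxt
      }
      list(o = head_id, kind = "blank")
    }
    else stop("turtle parse error: unexpected object token ", t$type)
  }
  parse_verb <- function() {
    t <- advance()
    if (t$type == "a") rdf_uri("type")
    else if (t$type == "iri") t$value
    else if (t$type == "pname") resolve_pname(t$value)
    else stop("turtle parse error: unexpected verb token ", t$type)
  }
  parse_pol <- function(subj) {
    repeat {
      p <- parse_verb()
      repeat {
        ob <- parse_object()
        emit(subj, p, ob$o, ob$kind, ob$dt %||% NA_character_)
        if (peek()$type == ",") advance() else break
      }
      if (peek()$type == ";") {
        advance()
        if (peek()$type %in% c(".", "]")) break
      } else break
    }
  }
  while (peek()$type != "eof") {
    t <- peek()
    if (t$type == "directive") {
      advance()
      pn <- expect("pname")
      pre <- sub(":.*$", "", pn$value)
      iri <- expect("iri")
      prefixes[pre] <- iri$value
      if (peek()$type == ".") advance()
      next
    }
    subj <- {
      tt <- advance()
      if (tt$type == "iri") tt$value
      else if (tt$type == "pname") resolve_pname(tt$value)
      else if (tt$type == "[") {
        id <- new_blank()
        if (peek()$type != "]") parse_pol(id)
        expect("]")
        id
      }
      else stop("turtle parse error: unexpected subject token ", tt$type)
    }
    if (peek()$type != ".") parse_pol(subj)
    expect(".")
  }
  df <- if (length(rows)) do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE))) else triple_frame()
  attr(df, "prefixes") <- prefixes
  df
}

## ---- RDF/XML reader (ontology documents) ----------------------------------

parse_rdfxml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("RDF/XML parse error: ",
                                           conditionMessage(e), call. = FALSE))
  rows <- list()
  ns <- xml2::xml_ns(doc)
  expand <- function(node) {
    ## full URI of an element = namespace + local name
    q <- xml2::xml_name(node, ns = ns)
    parts <- strsplit(q, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L) paste0(unname(ns[parts[1]]), parts[2]) else q
  }
  for (top in xml2::xml_children(xml2::xml_root(doc))) {
    s <- xml2::xml_attr(top, "about")
    if (is.na(s)) s <- xml2::xml_attr(top, "ID")
    if (is.na(s)) next
    tname <- expand(top)
    if (tname != rdf_uri("Description"))
      rows[[length(rows) + 1L]] <- list(s = s, p = rdf_uri("type"), o = tname,
                                        o_kind = "uri", o_datatype = NA_character_)
    for (pe in xml2::xml_children(top)) {
      p <- expand(pe)
      res <- xml2::xml_attr(pe, "resource")
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <- list(s = s, p = p, o = res, o_kind = "uri",
                                          o_datatype = NA_character_)
      } else if (length(xml2::xml_children(pe)) == 0L) {
        dt <- xml2::xml_attr(pe, "datatype")
        rows[[length(rows) + 1L]] <- list(s = s, p = p, o = xml2::xml_text(pe),
                                          o_kind = "literal",
                                          o_datatype = if (is.na(dt)) xsd_uri("string") else dt)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE))) else triple_frame()
  attr(df, "prefixes") <- character(0)
  df
}

## ---- canonical writers -----------------------------------------------------

## Compress a URI to a CURIE when a declared prefix base matches and the
## remainder is a safe local name; otherwise keep <uri>.
curie_or_iri <- function(uri, prefixes) {
  if (length(prefixes)) {
    ord <- order(nchar(prefixes), decreasing = TRUE)
    for (k in ord) {
      base <- prefixes[[k]]
      if (startsWith(uri, base)) {
        loc <- substring(uri, nchar(base) + 1L)
        if (grepl("^[A-Za-z_][A-Za-z0-9_\\-]*$", loc))
          return(paste0(names(prefixes)[k], ":", loc))
      }
    }
  }
  paste0("<", uri, ">")
}

ttl_literal <- function(value, datatype) {
  esc <- gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", value))
  if (is.na(datatype) || datatype == xsd_uri("string"))
    paste0("\"", esc, "\"")
  else
    paste0("\"", esc, "\"^^", curie_or_iri(datatype, STD_PREFIXES))
}

STD_PREFIXES <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS)

## Serialize a triple frame (no blank nodes) canonically: subjects, then
## predicates, then objects in C-locale lexicographic order.
write_turtle_triples <- function(df, prefixes, extra_lines = character(0)) {
  prefixes <- c(STD_PREFIXES, prefixes[setdiff(names(prefixes), names(STD_PREFIXES))])
  prefixes <- prefixes[c_order(names(prefixes))]
  out <- paste0("@prefix ", names(prefixes), ": <", unname(prefixes), "> .")
  body <- character(0)
  if (nrow(df)) {
    okey <- ifelse(df$o_kind == "literal",
                   paste0("2", df$o, "", df$o_datatype),
                   paste0("1", df$o))
    df <- df[c_order(df$s, df$p, okey), , drop = FALSE]
    df <- df[!duplicated(df[c("s", "p", "o", "o_kind", "o_datatype")]), , drop = FALSE]
    for (s in unique(df$s)) {
      sd <- df[df$s == s, , drop = FALSE]
      lines <- character(0)
      for (p in unique(sd$p)) {
        pd <- sd[sd$p == p, , drop = FALSE]
        objs <- vapply(seq_len(nrow(pd)), function(i) {
          if (pd$o_kind[i] == "literal") ttl_literal(pd$o[i], pd$o_datatype[i])
          else if (pd$o_kind[i] == "expr")
            render_expr_ttl(expr_from_key(pd$o[i]), prefixes)
          else curie_or_iri(pd$o[i], prefixes)
        }, character(1))
        pv <- if (p == rdf_uri("type")) "a" else curie_or_iri(p, prefixes)
        lines <- c(lines, paste0("    ", pv, " ", paste(objs, collapse = ", ")))
      }
      body <- c(body, paste0(curie_or_iri(s, prefixes), "\n",
                             paste(lines, collapse = " ;\n"), " ."))
    }
  }
  paste(c(out, "", body, extra_lines), collapse = "\n")
}
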