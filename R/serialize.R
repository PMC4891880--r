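## Canonical serialization of a knowledge base: equal KBs (set equality of
## individuals, assertions and links) serialize byte-identically, and
## serialize -> load -> serialize is a fixed point for Turtle.

kb_to_triples <- function(kb, profile = c("rdf", "owl")) {
  profile <- match.arg(profile)
  rows <- list()
  emit <- function(s, p, o, kind, dt = NA_character_)
    rows[[length(rows) + 1L]] <<- data.frame(s = s, p = p, o = o, o_kind = kind,
                                             o_datatype = dt,
                                             stringsAsFactors = FALSE)
  for (uri in c_sort(names(kb$individuals))) {
    ind <- kb$individuals[[uri]]
    for (cl in ind$classes) emit(uri, rdf_uri("type"), cl, "uri")
    for (i in seq_len(nrow(ind$data)))
      emit(uri, ind$data$property[i], ind$data$value[i], "literal",
           ind$data$datatype[i])
    for (i in seq_len(nrow(ind$objects)))
      emit(uri, ind$objects$property[i], ind$objects$object[i], "uri")
    if (profile == "owl") {
      ## anonymous expressions travel as their canonical full-URI key;
      ## each writer renders them in its own syntax
      for (e in ind$exprs)
        emit(uri, rdf_uri("type"), expr_key(e), "expr")
    }
  }
  for (i in seq_len(nrow(kb$same_as)))
    emit(kb$same_as[i, 1], owl_uri("sameAs"), kb$same_as[i, 2], "uri")
  if (profile == "owl") {
    for (i in seq_len(nrow(kb$different_from)))
      emit(kb$different_from[i, 1], owl_uri("differentFrom"),
           kb$different_from[i, 2], "uri")
  }
  if (length(rows)) do.call(rbind, rows) else triple_frame()
}

expr_from_key <- function(key) {
  pe <- parse_class_expr_text(key)
  class_expr(pe$classes, pe$restrictions)
}

render_expr_ttl <- function(e, prefixes) {
  px <- c(STD_PREFIXES, prefixes[setdiff(names(prefixes), names(STD_PREFIXES))])
  term <- function(u) curie_or_iri(u, px)
  items <- c(vapply(e$classes, term, character(1), USE.NAMES = FALSE),
             vapply(e$restrictions, function(r)
               paste0("[ a owl:Restriction ; owl:onProperty ", term(r$property),
                      " ; owl:someValuesFrom ", term(r$filler), " ]"),
               character(1)))
  paste0("[ a owl:Class ; owl:intersectionOf ( ",
         paste(items, collapse = " "), " ) ]")
}

#' Serialize a knowledge base
#'
#' Canonical ordering (subjects, then predicates, then objects,
#' lexicographic by URI/literal in the C locale) so equal knowledge bases
#' serialize byte-identically. Profile "owl" additionally emits
#' class-membership for anonymous class expressions and owl:differentFrom
#' axioms; profile "rdf" emits the ground assertions and owl:sameAs links
#' only. Serialization refuses if the KB fails [check_consistency()],
#' unless `override` is set.
#'
#' @param kb a [knowledge_base()].
#' @param format "turtle" or "rdfxml".
#' @param profile "rdf" or "owl".
#' @param override serialize even with violations present.
#' @return document text.
#' @export
serialize_kb <- function(kb, format = c("turtle", "rdfxml"),
                         profile = c("rdf", "owl"), override = FALSE) {
  format <- match.arg(format)
  profile <- match.arg(profile)
  if (!override) {
    rep <- check_consistency(kb)
    if (nrow(rep))
      stop("refuse-to-serialize: ", nrow(rep),
           " consistency violation(s) present; first: ", rep$kind[1], " on ",
           rep$subject[1])
  }
  tr <- kb_to_triples(kb, profile)
  if (format == "turtle")
    paste0(write_turtle_triples(tr, kb$ontology$prefixes), "\n")
  else
    write_rdfxml_triples(tr, kb$ontology$prefixes)
}

write_rdfxml_triples <- function(df, prefixes) {
  px <- c(STD_PREFIXES, prefixes[setdiff(names(prefixes), names(STD_PREFIXES))])
  px <- px[c_order(names(px))]
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  qname <- function(uri) {
    for (k in order(nchar(px), decreasing = TRUE)) {
      base <- px[[k]]
      if (startsWith(uri, base)) {
        loc <- substring(uri, nchar(base) + 1L)
        if (grepl("^[A-Za-z_][A-Za-z0-9_\\-]*$", loc))
          return(paste0(names(px)[k], ":", loc))
      }
    }
    NA_character_
  }
  header <- paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n<rdf:RDF",
                   paste0("\n    xmlns:", names(px), "=\"", unname(px), "\"",
                          collapse = ""), ">")
  body <- character(0)
  if (nrow(df)) {
    df <- df[df$o_kind != "expr" | TRUE, , drop = FALSE]
    okey <- ifelse(df$o_kind == "literal", paste0("2", df$o), paste0("1", df$o))
    df <- df[c_order(df$s, df$p, okey), , drop = FALSE]
    df <- unique(df)
    for (s in unique(df$s)) {
      sd <- df[df$s == s, , drop = FALSE]
      lines <- paste0("  <rdf:Description rdf:about=\"", esc(s), "\">")
      for (i in seq_len(nrow(sd))) {
        pq <- qname(sd$p[i])
        if (is.na(pq)) next  # predicate outside declared namespaces
        if (sd$o_kind[i] == "uri") {
          lines <- c(lines, paste0("    <", pq, " rdf:resource=\"",
                                   esc(sd$o[i]), "\"/>"))
        } else if (sd$o_kind[i] == "literal") {
          dt <- sd$o_datatype[i]
          dta <- if (!is.na(dt) && dt != xsd_uri("string"))
            paste0(" rdf:datatype=\"", esc(dt), "\"") else ""
          lines <- c(lines, paste0("    <", pq, dta, ">", esc(sd$o[i]),
                                   "</", pq, ">"))
        } else {
          ## anonymous class expression membership
          lines <- c(lines, render_expr_rdfxml(sd$o[i]))
        }
      }
      body <- c(body, c(lines, "  </rdf:Description>"))
    }
  }
  paste0(paste(c(header, body, "</rdf:RDF>"), collapse = "\n"), "\n")
}

render_expr_rdfxml <- function(key) {
  e <- expr_from_key(key)
  items <- c(
    vapply(e$classes, function(cu)
      paste0("        <rdf:Description rdf:about=\"", cu, "\"/>"), character(1)),
    vapply(e$restrictions, function(r)
      paste0("        <owl:Restriction>\n",
             "          <owl:onProperty rdf:resource=\"", r$property, "\"/>\n",
             "          <owl:someValuesFrom rdf:resource=\"", r$filler, "\"/>\n",
             "        </owl:Restriction>"), character(1)))
  paste0("    <rdf:type>\n      <owl:Class>\n",
         "        <owl:intersectionOf rdf:parseType=\"Collection\">\n",
         paste(items, collapse = "\n"),
         "\n        </owl:intersectionOf>\n      </owl:Class>\n    </rdf:type>")
}

## Rebuild a class_expr from parsed triples rooted at blank node `root`.
expr_from_triples <- function(tr, root) {
  classes <- character(0); restrictions <- list()
  handle_item <- function(node, kind) {
    if (kind == "uri") { classes <<- c(classes, node); return(invisible()) }
    types <- tr$o[tr$s == node & tr$p == rdf_uri("type")]
    if (owl_uri("Restriction") %in% types) {
      p <- tr$o[tr$s == node & tr$p == owl_uri("onProperty")][1]
      f <- tr$o[tr$s == node & tr$p == owl_uri("someValuesFrom")][1]
      restrictions[[length(restrictions) + 1L]] <<-
        list(property = p, filler = f)
    }
  }
  lst <- tr[tr$s == root & tr$p == owl_uri("intersectionOf"), , drop = FALSE]
  if (nrow(lst)) {
    cur <- lst$o[1]
    while (cur != rdf_uri("nil")) {
      fi <- tr[tr$s == cur & tr$p == rdf_uri("first"), , drop = FALSE]
      if (nrow(fi)) handle_item(fi$o[1], fi$o_kind[1])
      re <- tr$o[tr$s == cur & tr$p == rdf_uri("rest")]
      cur <- if (length(re)) re[1] else rdf_uri("nil")
    }
  } else {
    ## bare restriction without intersection wrapper
    handle_item(root, "blank")
  }
  class_expr(classes, restrictions)
}

#' Load a serialized knowledge base
#'
#' Reconstructs individuals, their assertions, anonymous class-expression
#' memberships and sameAs/differentFrom links from a Turtle document,
#' classified against the given ontology (datatype vs object properties).
#' Loaded individuals carry provenance `(source_id="loaded", entity="",
#' local_id=<uri>)`.
#'
#' @param document Turtle text.
#' @param onto the [ontology_model()] the dataset was generated against.
#' @return a [knowledge_base()].
#' @export
load_kb <- function(document, onto) {
  tr <- parse_turtle(document)
  inds <- list()
  same <- list(); diff <- list()
  blank <- startsWith(tr$s, "_:")
  subjects <- unique(tr$s[!blank])
  get_ind <- function(u) {
    if (is.null(inds[[u]]))
      inds[[u]] <<- individual(u, provenance = data.frame(
        source_id = "loaded", entity = "", local_id = u,
        stringsAsFactors = FALSE))
    inds[[u]]
  }
  for (i in seq_len(nrow(tr))) {
    s <- tr$s[i]
    if (startsWith(s, "_:")) next
    p <- tr$p[i]; o <- tr$o[i]; kind <- tr$o_kind[i]
    if (p == rdf_uri("type")) {
      ind <- get_ind(s)
      if (kind == "uri") {
        if (!is.null(onto$classes[[o]]))
          ind$classes <- unique(c(ind$classes, o))
      } else if (kind == "blank") {
        ind$exprs <- c(ind$exprs, list(expr_from_triples(tr, o)))
      }
      inds[[s]] <- ind
    } else if (p == owl_uri("sameAs")) {
      same[[length(same) + 1L]] <- c(s, o)
    } else if (p == owl_uri("differentFrom")) {
      diff[[length(diff) + 1L]] <- c(s, o)
    } else if (kind == "literal" && !is.null(onto$dprops[[p]])) {
      ind <- get_ind(s)
      ind$data <- unique(rbind(ind$data, data.frame(
        property = p, value = o, datatype = tr$o_datatype[i],
        stringsAsFactors = FALSE)))
      inds[[s]] <- ind
    } else if (kind == "uri" && !is.null(onto$oprops[[p]])) {
      ind <- get_ind(s)
      ind$objects <- unique(rbind(ind$objects, data.frame(
        property = p, object = o, external = !(o %in% subjects),
        stringsAsFactors = FALSE)))
      inds[[s]] <- ind
    }
  }
  ## dedup expressions per individual
  for (u in names(inds)) {
    ex <- inds[[u]]$exprs
    inds[[u]]$exprs <- ex[!duplicated(vapply(ex, expr_key, character(1)))]
  }
  knowledge_base(onto, inds,
                 same_as = if (length(same)) do.call(rbind, same) else NULL,
                 different_from = if (length(diff)) do.call(rbind, diff) else NULL)
}
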