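## ontology_kb (declaration side): the target OWL ontology as a structural
## model - classes, datatype/object properties with domains and ranges,
## disjointness, the subclass partial order, and prefix bindings.

#' Construct an ontology model
#'
#' @param classes named list (by URI) of `list(uri, label)`.
#' @param dprops named list (by URI) of datatype properties
#'   `list(uri, label, domain, range)` where `range` is an xsd datatype URI.
#' @param oprops named list (by URI) of object properties
#'   `list(uri, label, domain, range)` where domain/range are class URIs.
#' @param disjoint list of length-2 character vectors of class URIs
#'   (held symmetrically).
#' @param subclass named list: child class URI -> character vector of
#'   direct parent URIs. Must be acyclic.
#' @param prefixes named character vector: prefix label -> URI base.
#' @param capability character vector of notes about axiom kinds seen in a
#'   source document but not captured by the structural model.
#' @return object of class `ontology_model`.
#' @export
ontology_model <- function(classes = list(), dprops = list(), oprops = list(),
                           disjoint = list(), subclass = list(),
                           prefixes = character(0), capability = character(0)) {
  ## symmetric closure of disjointness
  if (length(disjoint)) {
    disjoint <- unique(lapply(disjoint, function(p) c_sort(p)))
  }
  ## acyclicity of subclass
  if (length(subclass)) {
    visit <- function(u, stack) {
      if (u %in% stack) stop("subclass relation is cyclic at ", u)
      for (p in subclass[[u]] %||% character(0)) visit(p, c(stack, u))
    }
    for (u in names(subclass)) visit(u, character(0))
  }
  structure(list(classes = classes, dprops = dprops, oprops = oprops,
                 disjoint = disjoint, subclass = subclass,
                 prefixes = prefixes, capability = capability),
            class = "ontology_model")
}

#' @export
print.ontology_model <- function(x, ...) {
  cat("<ontology_model> ", length(x$classes), " classes, ",
      length(x$dprops), " datatype props, ", length(x$oprops),
      " object props, ", length(x$disjoint), " disjoint pairs\n", sep = "")
  invisible(x)
}

#' Load an OWL ontology document
#'
#' Captures class, property (with domain/range), disjointness and named
#' subclass declarations from RDF/XML or Turtle. Axiom kinds outside the
#' structural model are recorded in the model's `capability` report, never
#' dropped silently. Properties without a declared domain or range produce
#' a warning; checks involving the missing side are skipped downstream.
#'
#' @param document ontology text.
#' @param format "turtle" or "rdfxml".
#' @return an [ontology_model()].
#' @export
load_ontology <- function(document, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  tr <- if (format == "turtle") parse_turtle(document) else parse_rdfxml(document)
  prefixes <- attr(tr, "prefixes") %||% character(0)
  classes <- list(); dprops <- list(); oprops <- list()
  disjoint <- list(); subclass <- list(); capability <- character(0)

  if (nrow(tr) == 0L) {
    warning("empty ontology document", call. = FALSE)
    return(ontology_model(prefixes = prefixes))
  }
  typ <- tr[tr$p == rdf_uri("type") & tr$o_kind == "uri", , drop = FALSE]
  labels <- tr[tr$p == rdfs_uri("label") & tr$o_kind == "literal", , drop = FALSE]
  label_of <- function(uri) {
    hit <- labels$o[labels$s == uri]
    if (length(hit)) hit[[1]] else uri_local_name(uri)
  }
  of_type <- function(t) unique(typ$s[typ$o == owl_uri(t)])
  for (u in of_type("Class"))
    classes[[u]] <- list(uri = u, label = label_of(u))
  prop_fields <- function(u) {
    dom <- tr$o[tr$s == u & tr$p == rdfs_uri("domain") & tr$o_kind == "uri"]
    rng <- tr$o[tr$s == u & tr$p == rdfs_uri("range") & tr$o_kind == "uri"]
    list(uri = u, label = label_of(u),
         domain = if (length(dom)) dom[[1]] else NA_character_,
         range = if (length(rng)) rng[[1]] else NA_character_)
  }
  for (u in of_type("DatatypeProperty")) {
    f <- prop_fields(u)
    if (is.na(f$domain) || is.na(f$range))
      warning("property ", u, " lacks declared domain/range; related checks skipped",
              call. = FALSE)
    dprops[[u]] <- f
  }
  for (u in of_type("ObjectProperty")) {
    f <- prop_fields(u)
    if (is.na(f$domain) || is.na(f$range))
      warning("property ", u, " lacks declared domain/range; related checks skipped",
              call. = FALSE)
    oprops[[u]] <- f
  }
  dj <- tr[tr$p == owl_uri("disjointWith") & tr$o_kind == "uri", , drop = FALSE]
  for (i in seq_len(nrow(dj)))
    disjoint[[length(disjoint) + 1L]] <- c(dj$s[i], dj$o[i])
  sc <- tr[tr$p == rdfs_uri("subClassOf"), , drop = FALSE]
  for (i in seq_len(nrow(sc))) {
    if (sc$o_kind[i] != "uri") {
      capability <- c(capability, paste0("anonymous superclass of ", sc$s[i],
                                         " not captured"))
      next
    }
    subclass[[sc$s[i]]] <- unique(c(subclass[[sc$s[i]]] %||% character(0), sc$o[i]))
  }
  consumed <- c(rdf_uri("type"), rdfs_uri("label"), rdfs_uri("domain"),
                rdfs_uri("range"), rdfs_uri("subClassOf"), owl_uri("disjointWith"),
                rdfs_uri("comment"))
  other <- setdiff(unique(tr$p), consumed)
  other <- other[!startsWith(other, RDF_NS)]
  if (length(other))
    capability <- c(capability,
                    paste0("axioms with predicate ", other, " not captured"))
  ## declarations of kinds we do not model
  other_types <- setdiff(unique(typ$o),
                         c(owl_uri("Class"), owl_uri("DatatypeProperty"),
                           owl_uri("ObjectProperty"), owl_uri("Ontology"),
                           owl_uri("NamedIndividual")))
  if (length(other_types))
    capability <- c(capability, paste0("declarations of type ", other_types,
                                       " not captured"))
  m <- ontology_model(classes, dprops, oprops, disjoint, subclass, prefixes,
                      capability)
  attr(m, "source_digest") <- paste0(length(classes), "/", length(dprops), "/",
                                     length(oprops), "/",
                                     paste(c_sort(names(classes)), collapse = ","))
  m
}

## ---- name resolution -------------------------------------------------------

#' Resolve a name to a declared ontology term URI
#'
#' Accepts an absolute URI, a CURIE against the ontology's (or extra)
#' prefixes, or a bare local name / label matched against declarations of
#' the requested kind.
#'
#' @param onto an [ontology_model()].
#' @param name the name to resolve.
#' @param kind "class", "dprop", "oprop", "property" (either kind) or "any".
#' @param prefixes extra prefix bindings consulted before the ontology's.
#' @return the URI, or NA_character_ if unresolved.
#' @export
onto_lookup <- function(onto, name, kind = "any", prefixes = character(0)) {
  pool <- switch(kind,
    class = names(onto$classes),
    dprop = names(onto$dprops),
    oprop = names(onto$oprops),
    property = c(names(onto$dprops), names(onto$oprops)),
    any = c(names(onto$classes), names(onto$dprops), names(onto$oprops)))
  if (is_absolute_http(name))
    return(if (name %in% pool) name else NA_character_)
  px <- c(prefixes, onto$prefixes)
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    base <- px[parts[1]]
    if (!is.na(base)) {
      uri <- paste0(unname(base), paste(parts[-1], collapse = ":"))
      return(if (uri %in% pool) uri else NA_character_)
    }
    ## fall through: maybe the local part matches by name
    name <- parts[length(parts)]
  }
  locals <- vapply(pool, uri_local_name, character(1))
  hit <- pool[locals == name]
  if (length(hit) == 0L) {
    lbls <- vapply(pool, function(u) {
      rec <- onto$classes[[u]] %||% onto$dprops[[u]] %||% onto$oprops[[u]]
      rec$label %||% ""
    }, character(1))
    hit <- pool[lbls == name]
  }
  if (length(hit) >= 1L) hit[[1]] else NA_character_
}

## superclass closure (reflexive)
ancestors_of <- function(onto, class_uri) {
  seen <- character(0)
  stack <- class_uri
  while (length(stack)) {
    u <- stack[[1]]; stack <- stack[-1]
    if (u %in% seen) next
    seen <- c(seen, u)
    stack <- c(stack, onto$subclass[[u]] %||% character(0))
  }
  seen
}

classes_disjoint <- function(onto, a, b) {
  aa <- ancestors_of(onto, a); bb <- ancestors_of(onto, b)
  for (p in onto$disjoint) {
    if ((p[1] %in% aa && p[2] %in% bb) || (p[1] %in% bb && p[2] %in% aa))
      return(TRUE)
  }
  FALSE
}

## ---- anonymous class expressions (intersection + existential only) --------

#' Construct an anonymous class expression
#'
#' Only the two forms the engine materializes are supported: an
#' intersection of named classes and existential restrictions
#' (`C and P some D`).
#'
#' @param classes character vector of named conjunct class URIs.
#' @param restrictions list of `list(property=, filler=)` existential
#'   restrictions (URIs).
#' @return object of class `class_expr`.
#' @export
class_expr <- function(classes = character(0), restrictions = list()) {
  structure(list(classes = c_sort(unique(classes)),
                 restrictions = restrictions[c_order(
                   vapply(restrictions, function(r) paste0(r$property, "|", r$filler),
                          character(1)))]),
            class = "class_expr")
}

expr_key <- function(e) {
  paste0("(", paste(c(e$classes,
                      vapply(e$restrictions, function(r)
                        paste0(r$property, " some ", r$filler), character(1))),
                    collapse = " and "), ")")
}

## Parse the textual form used in patterns: "Name" or
## "(Name and prop some Name [and prop some Name ...])".
## Names are resolved against the ontology lazily by the caller; here we
## keep raw names.
parse_class_expr_text <- function(txt) {
  txt <- trimws(gsub("\\s+", " ", txt))
  if (!startsWith(txt, "("))
    return(list(classes = txt, restrictions = list()))
  inner <- sub("^\\(", "", sub("\\)$", "", txt))
  parts <- trimws(strsplit(inner, "\\band\\b")[[1]])
  classes <- character(0); restrictions <- list()
  for (p in parts) {
    if (!nzchar(p)) next
    m <- regmatches(p, regexec("^(\\S+)\\s+some\\s+(\\S+)$", p))[[1]]
    if (length(m)) restrictions[[length(restrictions) + 1L]] <-
        list(property = m[2], filler = m[3])
    else classes <- c(classes, p)
  }
  list(classes = classes, restrictions = restrictions)
}
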