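## ontology_kb (instance side): the growing knowledge base of generated
## individuals, URI minting, axiom batches and the structural consistency
## check set (disjointness, datatype ranges, object domain/range as
## asserted-type checks, sameAs/differentFrom clash).

empty_data_frame <- function() {
  data.frame(property = character(), value = character(),
             datatype = character(), stringsAsFactors = FALSE)
}
empty_object_frame <- function() {
  data.frame(property = character(), object = character(),
             external = logical(), stringsAsFactors = FALSE)
}
empty_prov_frame <- function() {
  data.frame(source_id = character(), entity = character(),
             local_id = character(), stringsAsFactors = FALSE)
}

#' Construct an ontology individual
#'
#' @param uri absolute HTTP URI.
#' @param classes character vector of asserted named class URIs.
#' @param exprs list of anonymous [class_expr()] memberships.
#' @param data data.frame(property, value, datatype) of data assertions;
#'   `datatype` is an xsd datatype URI.
#' @param objects data.frame(property, object, external) of object
#'   assertions; `external` marks targets outside the knowledge base.
#' @param provenance data.frame(source_id, entity, local_id); non-empty for
#'   every generated individual.
#' @return object of class `individual`.
#' @export
individual <- function(uri, classes = character(0), exprs = list(),
                       data = empty_data_frame(),
                       objects = empty_object_frame(),
                       provenance = empty_prov_frame()) {
  stopifnot(is_absolute_http(uri))
  structure(list(uri = uri, classes = c_sort(unique(classes)),
                 exprs = sort_exprs(exprs),
                 data = sort_frame(unique(data)),
                 objects = sort_frame(unique(objects)),
                 provenance = sort_frame(unique(provenance))),
            class = "individual")
}

## assertion frames are sets: keep them canonically ordered so KB equality
## is plain identical() and serialization is order-insensitive
sort_frame <- function(df) {
  if (is.null(df) || nrow(df) == 0L) { rownames(df) <- NULL; return(df) }
  key <- do.call(paste, c(lapply(df, as.character), sep = "\r"))
  df <- df[c_order(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

sort_exprs <- function(exprs) {
  if (length(exprs) < 2L) return(exprs)
  exprs[c_order(vapply(exprs, expr_key, character(1)))]
}

#' @export
print.individual <- function(x, ...) {
  cat("<individual> ", x$uri, "\n  classes: ",
      paste(vapply(x$classes, uri_local_name, character(1)), collapse = ", "),
      "\n  ", nrow(x$data), " data / ", nrow(x$objects),
      " object assertions\n", sep = "")
  invisible(x)
}

merge_individual_records <- function(a, b) {
  stopifnot(a$uri == b$uri)
  ex <- c(a$exprs, b$exprs)
  ex <- ex[!duplicated(vapply(ex, expr_key, character(1)))]
  individual(a$uri,
             classes = unique(c(a$classes, b$classes)),
             exprs = ex,
             data = unique(rbind(a$data, b$data)),
             objects = unique(rbind(a$objects, b$objects)),
             provenance = unique(rbind(a$provenance, b$provenance)))
}

#' Construct a knowledge base
#'
#' @param ontology an [ontology_model()].
#' @param individuals named list (by URI) of [individual()] objects.
#' @param same_as,different_from 2-column character matrices of unordered
#'   URI pairs. The two sets must be disjoint.
#' @return object of class `knowledge_base`.
#' @export
knowledge_base <- function(ontology, individuals = list(),
                           same_as = NULL, different_from = NULL) {
  same_as <- normalize_pairs(same_as)
  different_from <- normalize_pairs(different_from)
  if (nrow(same_as) && nrow(different_from)) {
    ka <- paste(same_as[, 1], same_as[, 2])
    kd <- paste(different_from[, 1], different_from[, 2])
    if (length(intersect(ka, kd)))
      stop("same_as and different_from share a pair")
  }
  structure(list(ontology = ontology, individuals = individuals,
                 same_as = same_as, different_from = different_from),
            class = "knowledge_base")
}

normalize_pairs <- function(p) {
  if (is.null(p) || (is.matrix(p) && nrow(p) == 0L))
    return(matrix(character(0), ncol = 2))
  if (!is.matrix(p)) p <- matrix(p, ncol = 2, byrow = TRUE)
  p <- t(apply(p, 1L, c_sort))
  p <- p[p[, 1] != p[, 2], , drop = FALSE]       # self-pairs are no-ops
  unique(p)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base> ", length(x$individuals), " individuals, ",
      nrow(x$same_as), " sameAs pairs, ", nrow(x$different_from),
      " differentFrom pairs\n", sep = "")
  invisible(x)
}

#' sameAs closure representatives
#'
#' @param kb a [knowledge_base()].
#' @return named character vector mapping each URI participating in a
#'   sameAs pair to its component representative (lexicographically
#'   smallest member).
#' @export
sameas_representatives <- function(kb) uf_components(kb$same_as)

canon_uri <- function(uri, reps) {
  r <- reps[uri]
  ifelse(is.na(r), uri, unname(r))
}

## ---- URI policy ------------------------------------------------------------

#' Construct a URI minting policy
#'
#' Minted-local URIs take the shape `base + ClassLocalName + "/" +
#' percent-encoded token`; adopt-external URIs take `base + encoded token`,
#' which lets a class reuse an external authority's URI scheme (e.g.
#' UniProt accession URIs).
#'
#' @param default_base URI base used for classes without their own entry.
#' @param per_class_base named character vector: class URI -> base.
#' @param mode named character vector: class URI -> "mint-local" or
#'   "adopt-external" (default mint-local).
#' @return object of class `uri_policy`.
#' @export
uri_policy <- function(default_base, per_class_base = character(0),
                       mode = character(0)) {
  for (b in c(default_base, per_class_base)) {
    if (!is_absolute_http(b) || !grepl("[/#]$", b))
      stop("URI base must be an absolute HTTP URI ending in '/' or '#': ", b)
  }
  stopifnot(all(mode %in% c("mint-local", "adopt-external")))
  structure(list(default_base = default_base, per_class_base = per_class_base,
                 mode = mode),
            class = "uri_policy")
}

#' Mint a deterministic URI for an individual
#'
#' @param policy a [uri_policy()].
#' @param class_ref class URI (or a list with a `uri` field).
#' @param token non-empty identifying token; percent-encoded into the URI.
#' @return absolute HTTP URI.
#' @export
mint_uri <- function(policy, class_ref, token) {
  if (is.list(class_ref)) class_ref <- class_ref$uri
  if (!is.character(token) || length(token) != 1L || !nzchar(token))
    stop("mint_uri: empty token")
  base <- policy$per_class_base[class_ref]
  if (is.na(base)) base <- policy$default_base else base <- unname(base)
  mode <- policy$mode[class_ref]
  if (is.na(mode)) mode <- "mint-local"
  if (mode == "adopt-external")
    paste0(base, pct_encode(token))
  else
    paste0(base, uri_local_name(class_ref), "/", pct_encode(token))
}

## ---- axiom batches ---------------------------------------------------------

#' Construct an axiom batch
#'
#' The unit of admission to the knowledge base: new individuals plus
#' class-membership, data and object assertions. Batches are sets; applying
#' a batch is idempotent and order-independent.
#'
#' @param individuals list of [individual()] objects.
#' @param class_assert list of `list(subject=, class=)` where `class` is a
#'   class URI or a [class_expr()].
#' @param data data.frame(subject, property, value, datatype).
#' @param objects data.frame(subject, property, object, external).
#' @return object of class `axiom_batch`.
#' @export
axiom_batch <- function(individuals = list(), class_assert = list(),
                        data = NULL, objects = NULL) {
  if (is.null(data))
    data <- data.frame(subject = character(), property = character(),
                       value = character(), datatype = character(),
                       stringsAsFactors = FALSE)
  if (is.null(objects))
    objects <- data.frame(subject = character(), property = character(),
                          object = character(), external = logical(),
                          stringsAsFactors = FALSE)
  structure(list(individuals = individuals, class_assert = class_assert,
                 data = unique(data), objects = unique(objects)),
            class = "axiom_batch")
}

batch_subject_uris <- function(batch) {
  unique(c(vapply(batch$individuals, `[[`, character(1), "uri"),
           vapply(batch$class_assert, function(a) a$subject, character(1)),
           batch$data$subject, batch$objects$subject))
}

#' Apply an axiom batch to a knowledge base
#'
#' Idempotent: re-asserting existing content changes nothing. Assertions
#' must reference declared ontology terms; object targets must be batch
#' individuals, KB individuals, or flagged external.
#'
#' @param kb a [knowledge_base()].
#' @param batch an [axiom_batch()].
#' @return the updated [knowledge_base()].
#' @export
assert_axioms <- function(kb, batch) {
  onto <- kb$ontology
  inds <- kb$individuals
  known_class <- function(u) !is.null(onto$classes[[u]])
  for (ind in batch$individuals) {
    for (cl in ind$classes)
      if (!known_class(cl)) stop("unknown-term: class ", cl)
    inds[[ind$uri]] <- if (is.null(inds[[ind$uri]])) ind
                       else merge_individual_records(inds[[ind$uri]], ind)
  }
  target_ok <- function(uri, external) {
    external || !is.null(inds[[uri]])
  }
  for (a in batch$class_assert) {
    if (is.null(inds[[a$subject]]))
      stop("unknown-term: class assertion on absent individual ", a$subject)
    if (inherits(a$class, "class_expr")) {
      keys <- vapply(inds[[a$subject]]$exprs, expr_key, character(1))
      if (!expr_key(a$class) %in% keys)
        inds[[a$subject]]$exprs <- c(inds[[a$subject]]$exprs, list(a$class))
    } else {
      if (!known_class(a$class)) stop("unknown-term: class ", a$class)
      inds[[a$subject]]$classes <- unique(c(inds[[a$subject]]$classes, a$class))
    }
  }
  if (nrow(batch$data)) {
    for (p in unique(batch$data$property))
      if (is.null(onto$dprops[[p]])) stop("unknown-term: datatype property ", p)
    for (i in seq_len(nrow(batch$data))) {
      s <- batch$data$subject[i]
      if (is.null(inds[[s]])) stop("unknown-term: data assertion on absent individual ", s)
      inds[[s]]$data <- unique(rbind(inds[[s]]$data,
        data.frame(property = batch$data$property[i],
                   value = batch$data$value[i],
                   datatype = batch$data$datatype[i],
                   stringsAsFactors = FALSE)))
    }
  }
  if (nrow(batch$objects)) {
    for (p in unique(batch$objects$property))
      if (is.null(onto$oprops[[p]])) stop("unknown-term: object property ", p)
    for (i in seq_len(nrow(batch$objects))) {
      s <- batch$objects$subject[i]
      if (is.null(inds[[s]])) stop("unknown-term: object assertion on absent individual ", s)
      if (!target_ok(batch$objects$object[i], batch$objects$external[i]))
        stop("unknown-term: object assertion targets unknown individual ",
             batch$objects$object[i])
      inds[[s]]$objects <- unique(rbind(inds[[s]]$objects,
        data.frame(property = batch$objects$property[i],
                   object = batch$objects$object[i],
                   external = batch$objects$external[i],
                   stringsAsFactors = FALSE)))
    }
  }
  ## re-normalize touched individuals so set-equal KBs are identical()
  ## regardless of the order in which assertions arrived
  touched <- unique(c(vapply(batch$individuals, `[[`, character(1), "uri"),
                      vapply(batch$class_assert, function(a) a$subject,
                             character(1)),
                      batch$data$subject, batch$objects$subject))
  for (u in touched)
    inds[[u]] <- individual(inds[[u]]$uri, inds[[u]]$classes, inds[[u]]$exprs,
                            inds[[u]]$data, inds[[u]]$objects,
                            inds[[u]]$provenance)
  kb$individuals <- inds
  kb
}

## ---- structural consistency ------------------------------------------------

violation_frame <- function() {
  data.frame(kind = character(), subject = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' Check structural consistency of a knowledge base
#'
#' The built-in check set covers class disjointness (direct and inherited),
#' datatype-property range conformance, object-property domain/range as
#' asserted-type checks, and sameAs/differentFrom clashes. Violations are
#' results, not errors; an empty report means the KB is admissible under
#' the structural check set. Full OWL 2 DL reasoning is available only
#' through the external reasoner hook (see [run_config()]).
#'
#' @param kb a [knowledge_base()].
#' @param candidate optional [axiom_batch()]; when given, the check runs
#'   over KB plus candidate without mutating the KB.
#' @param subjects optional character vector restricting the per-individual
#'   checks to these URIs (the engine uses it to gate one candidate batch
#'   at a time; the check set is local to each subject, so restricting is
#'   sound).
#' @return data.frame(kind, subject, detail); zero rows iff admissible.
#' @export
check_consistency <- function(kb, candidate = NULL, subjects = NULL) {
  onto <- kb$ontology
  inds <- kb$individuals
  if (!is.null(candidate)) {
    for (ind in candidate$individuals)
      inds[[ind$uri]] <- if (is.null(inds[[ind$uri]])) ind
                         else merge_individual_records(inds[[ind$uri]], ind)
    for (a in candidate$class_assert) {
      if (is.null(inds[[a$subject]])) next
      if (inherits(a$class, "class_expr"))
        inds[[a$subject]]$exprs <- c(inds[[a$subject]]$exprs, list(a$class))
      else
        inds[[a$subject]]$classes <- unique(c(inds[[a$subject]]$classes, a$class))
    }
    for (i in seq_len(nrow(candidate$data))) {
      s <- candidate$data$subject[i]
      if (is.null(inds[[s]])) next
      inds[[s]]$data <- rbind(inds[[s]]$data, candidate$data[i, c("property", "value", "datatype")])
    }
    for (i in seq_len(nrow(candidate$objects))) {
      s <- candidate$objects$subject[i]
      if (is.null(inds[[s]])) next
      inds[[s]]$objects <- rbind(inds[[s]]$objects,
                                 candidate$objects[i, c("property", "object", "external")])
    }
  }
  viol <- list()
  add <- function(kind, subject, detail)
    viol[[length(viol) + 1L]] <<- data.frame(kind = kind, subject = subject,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  closure_cache <- new.env(parent = emptyenv())
  closure <- function(classes) {
    unique(unlist(lapply(classes, function(cl) {
      hit <- get0(cl, envir = closure_cache)
      if (is.null(hit)) {
        hit <- ancestors_of(onto, cl)
        assign(cl, hit, envir = closure_cache)
      }
      hit
    })))
  }
  scope <- if (is.null(subjects)) inds else inds[intersect(subjects, names(inds))]
  for (ind in scope) {
    cls <- closure(ind$classes)
    ## disjointness (direct and inherited)
    for (p in onto$disjoint) {
      if (p[1] %in% cls && p[2] %in% cls)
        add("disjointness", ind$uri,
            paste0("member of disjoint classes ", uri_local_name(p[1]), " and ",
                   uri_local_name(p[2])))
    }
    ## datatype ranges
    for (i in seq_len(nrow(ind$data))) {
      pr <- onto$dprops[[ind$data$property[i]]]
      if (is.null(pr) || is.na(pr$range)) next
      kind <- xsd_kind(pr$range)
      if (!kind_ok(ind$data$value[i], kind))
        add("datatype-range", ind$uri,
            paste0("value '", ind$data$value[i], "' of ",
                   uri_local_name(pr$uri), " is not ", kind))
    }
    ## object property domain / range as asserted-type checks
    for (i in seq_len(nrow(ind$objects))) {
      pr <- onto$oprops[[ind$objects$property[i]]]
      if (is.null(pr)) next
      if (!is.na(pr$domain) && length(ind$classes) &&
          !pr$domain %in% cls)
        add("object-domain", ind$uri,
            paste0("subject of ", uri_local_name(pr$uri),
                   " is not asserted into domain ", uri_local_name(pr$domain)))
      if (!is.na(pr$range)) {
        tgt <- inds[[ind$objects$object[i]]]
        if (!is.null(tgt) && length(tgt$classes) &&
            !pr$range %in% closure(tgt$classes))
          add("object-range", ind$uri,
              paste0("target ", ind$objects$object[i], " of ",
                     uri_local_name(pr$uri), " is not asserted into range ",
                     uri_local_name(pr$range)))
      }
    }
  }
  ## sameAs vs differentFrom through the closure
  if (nrow(kb$different_from)) {
    reps <- uf_components(kb$same_as)
    for (i in seq_len(nrow(kb$different_from))) {
      a <- canon_uri(kb$different_from[i, 1], reps)
      b <- canon_uri(kb$different_from[i, 2], reps)
      if (a == b)
        add("sameas-vs-differentfrom", kb$different_from[i, 1],
            paste0("pair with ", kb$different_from[i, 2],
                   " is both sameAs-connected and differentFrom"))
    }
  }
  if (length(viol)) unique(do.call(rbind, viol)) else violation_frame()
}

#' Export a violation report as JSON
#' @param report data frame returned by [check_consistency()].
#' @return JSON text.
#' @export
violations_json <- function(report) {
  as.character(jsonlite::toJSON(report, dataframe = "rows", auto_unbox = TRUE))
}
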