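## pattern_engine: ontology transformation patterns - templates of axiom
## statements over variables (the tuple <S, V>), with creating-variable
## detection and create() URI expressions. The grammar is the OPPL2-like
## subset spanning variable declarations (INDIVIDUAL/CONSTANT, optional
## create(?base.RENDERING+suffix)), BEGIN/ADD/END blocks, instanceOf with
## intersection/existential class expressions, and property additions.

#' Parse a transformation pattern
#'
#' @param text pattern source text.
#' @param name pattern name (defaults to "pattern").
#' @return object of class `owl_pattern` with fields `name`, `variables`
#'   (ordered list of `list(name, kind, generator)`) and `statements`.
#'   Constructs outside the subset (SELECT, REMOVE, arbitrary queries)
#'   raise an unsupported-construct error.
#' @export
parse_pattern <- function(text, name = "pattern") {
  for (bad in c("SELECT", "REMOVE"))
    if (grepl(paste0("\\b", bad, "\\b"), text))
      stop("unsupported-construct: ", bad)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  begin_at <- grep("^\\s*BEGIN\\s*$", lines)
  end_at <- grep("^\\s*END\\s*;?\\s*$", lines)
  if (length(begin_at) != 1L || length(end_at) != 1L || end_at <= begin_at)
    stop("pattern parse error: expected one BEGIN ... END; block")

  ## variable declarations: possibly several per line, comma-separated
  decl_text <- paste(lines[seq_len(begin_at - 1L)], collapse = "\n")
  decls <- regmatches(decl_text, gregexpr(
    "\\?[A-Za-z_][A-Za-z0-9_]*\\s*:\\s*(INDIVIDUAL|CONSTANT)(\\s*=\\s*create\\([^)]*\\))?",
    decl_text))[[1]]
  if (length(decls) == 0L) stop("pattern parse error: no variable declarations")
  variables <- lapply(decls, function(d) {
    m <- regmatches(d, regexec(
      "^(\\?[A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(INDIVIDUAL|CONSTANT)(\\s*=\\s*create\\(\\s*(\\?[A-Za-z_][A-Za-z0-9_]*)\\.RENDERING\\s*\\+\\s*([^)\\s]+)\\s*\\))?$",
      d))[[1]]
    if (length(m) == 0L) stop("pattern parse error: bad declaration '", d, "'")
    gen <- NULL
    if (nzchar(m[4])) {
      if (m[3 + 0] == "CONSTANT")
        stop("pattern parse error: create() on a CONSTANT variable")
      gen <- list(base_variable = m[5], suffix = m[6])
    }
    list(name = m[2], kind = m[3], generator = gen)
  })
  vnames <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(vnames))
    stop("pattern parse error: duplicate variable declaration")
  for (v in variables) {
    if (!is.null(v$generator)) {
      if (v$kind != "INDIVIDUAL")
        stop("pattern parse error: create() only on INDIVIDUAL variables")
      if (!v$generator$base_variable %in% vnames)
        stop("pattern parse error: create() base ", v$generator$base_variable,
             " not declared")
    }
  }

  body <- paste(lines[(begin_at + 1L):(end_at - 1L)], collapse = " ")
  body <- trimws(gsub("\\s+", " ", body))
  stmts_txt <- trimws(strsplit(body, ",(?=\\s*ADD\\b)", perl = TRUE)[[1]])
  stmts_txt <- stmts_txt[nzchar(stmts_txt)]
  if (length(stmts_txt) == 0L) stop("pattern parse error: empty BEGIN block")
  statements <- lapply(stmts_txt, function(st) {
    m <- regmatches(st, regexec(
      "^ADD\\s+(\\?[A-Za-z_][A-Za-z0-9_]*)\\s+(\\S+)\\s+(.*)$", st))[[1]]
    if (length(m) == 0L)
      stop("pattern parse error: bad statement '", st, "'")
    subj <- m[2]
    if (!subj %in% vnames)
      stop("pattern parse error: undeclared variable ", subj)
    if (m[3] == "instanceOf") {
      list(form = "instanceOf", var = subj, class_text = trimws(m[4]))
    } else {
      obj_txt <- trimws(m[4])
      obj <- if (startsWith(obj_txt, "?")) {
        if (!obj_txt %in% vnames)
          stop("pattern parse error: undeclared variable ", obj_txt)
        list(type = "var", value = obj_txt)
      } else if (grepl("^\".*\"$", obj_txt)) {
        list(type = "literal", value = substr(obj_txt, 2L, nchar(obj_txt) - 1L))
      } else list(type = "literal", value = obj_txt)
      list(form = "property", var = subj, property = m[3], object = obj)
    }
  })
  structure(list(name = name, variables = variables, statements = statements,
                 source = text),
            class = "owl_pattern")
}

#' @export
print.owl_pattern <- function(x, ...) {
  cat("<owl_pattern> ", x$name, ": ", length(x$variables), " variables, ",
      length(x$statements), " statements\n", sep = "")
  invisible(x)
}

pattern_var <- function(pattern, name) {
  for (v in pattern$variables) if (v$name == name) return(v)
  NULL
}

var_typed <- function(pattern, name) {
  any(vapply(pattern$statements, function(s)
    s$form == "instanceOf" && s$var == name, logical(1)))
}

#' Classify pattern variables as creating or referencing
#'
#' Creating variables are the INDIVIDUAL variables that generate new
#' individuals when the pattern is instantiated: those carrying a create()
#' expression, and those left unbound but typed by an instanceOf statement.
#' Referencing variables are bound to already-transformed source entities.
#' CONSTANT variables are never creating.
#'
#' @param pattern an [parse_pattern()] result.
#' @param binding a pattern binding (element of a rule set's
#'   `pattern_bindings`), or NULL for an empty binding.
#' @return list(creating = character vector, referencing = character vector).
#' @export
classify_variables <- function(pattern, binding = NULL) {
  bound <- if (is.null(binding)) character(0) else names(binding$vars)
  creating <- character(0); referencing <- character(0)
  for (v in pattern$variables) {
    if (v$kind == "CONSTANT") next
    if (!is.null(v$generator)) creating <- c(creating, v$name)
    else if (v$name %in% bound) referencing <- c(referencing, v$name)
    else if (var_typed(pattern, v$name)) creating <- c(creating, v$name)
    else stop("classification error: INDIVIDUAL variable ", v$name,
              " is unbound, generator-free and never typed")
  }
  list(creating = creating, referencing = referencing)
}

## statement's named class for a creating variable (first instanceOf)
creating_class_text <- function(pattern, var) {
  for (s in pattern$statements) {
    if (s$form == "instanceOf" && s$var == var) {
      pe <- parse_class_expr_text(s$class_text)
      if (length(pe$classes)) return(pe$classes[[1]])
    }
  }
  NA_character_
}

## ---- instance link graph (for variable binding across related records) ---

#' Build the undirected link graph over a set of data instances
#' @param instances list of [data_instance()].
#' @return list(nodes, adj) keyed by instance; used when a pattern variable
#'   is bound to an entity related (possibly over several links) to the
#'   pattern's context entity.
#' @export
instance_graph <- function(instances) {
  nodes <- list()
  for (ins in instances)
    nodes[[registry_key(ins$source_id, ins$entity, ins$local_id)]] <- ins
  adj <- lapply(nodes, function(x) character(0))
  for (ins in instances) {
    k <- registry_key(ins$source_id, ins$entity, ins$local_id)
    for (l in ins$links) {
      k2 <- registry_key(ins$source_id, l$target_entity, l$target_local_id)
      if (!is.null(nodes[[k2]])) {
        adj[[k]] <- c(adj[[k]], k2)
        adj[[k2]] <- c(adj[[k2]], k)
      }
    }
  }
  list(nodes = nodes, adj = lapply(adj, function(a) c_sort(unique(a))))
}

## nearest instance of `entity` reachable from `start` (breadth-first,
## deterministic); NULL if unreachable.
graph_find_entity <- function(graph, start_key, entity) {
  if (!is.null(graph$nodes[[start_key]]) &&
      graph$nodes[[start_key]]$entity == entity)
    return(graph$nodes[[start_key]])
  seen <- start_key
  frontier <- start_key
  while (length(frontier)) {
    nxt <- character(0)
    for (k in frontier) {
      for (k2 in graph$adj[[k]] %||% character(0)) {
        if (k2 %in% seen) next
        seen <- c(seen, k2)
        if (graph$nodes[[k2]]$entity == entity) return(graph$nodes[[k2]])
        nxt <- c(nxt, k2)
      }
    }
    frontier <- nxt
  }
  NULL
}

## ---- instantiation ---------------------------------------------------------

#' Instantiate a pattern for one context instance
#'
#' Creating variables become new individuals (create() renders the base
#' individual's URI token plus the suffix; fresh typed variables get a
#' deterministic token derived from the context instance); CONSTANT
#' variables resolve through [resolve_path()]; every statement is
#' instantiated into an [axiom_batch()]. Fixed content - statements with no
#' source-bound variable - is emitted for every instantiation: this is the
#' semantic-enrichment mechanism. Existential restrictions in instanceOf
#' expressions materialize one deterministic filler individual per subject
#' plus the anonymous-expression membership.
#'
#' @param pattern an [parse_pattern()] result.
#' @param binding the pattern binding to apply.
#' @param context list with fields `instance` (the driving
#'   [data_instance()]) and `graph` (an [instance_graph()] over the source).
#' @param registry named list mapping registry keys (with and without class
#'   qualifiers) to individual URIs.
#' @param policy a [uri_policy()].
#' @param onto the [ontology_model()].
#' @param tokens named character vector mapping individual URIs to their
#'   URI tokens (the RENDERING used by create()).
#' @return an [axiom_batch()], or an object of class `pattern_skip` whose
#'   `skip` attribute names the reason (unresolvable referenced individual
#'   or empty CONSTANT path).
#' @export
instantiate_pattern <- function(pattern, binding, context, registry, policy,
                                onto, tokens = character(0)) {
  inst <- context$instance
  graph <- context$graph
  cls <- classify_variables(pattern, binding)
  px <- attr(binding, "prefixes") %||% character(0)
  look <- function(name, kind) {
    u <- onto_lookup(onto, name, kind, px)
    if (is.na(u)) stop("unresolved pattern name '", name, "' (", kind, ")")
    u
  }
  skip <- function(reason) structure(list(), class = "pattern_skip",
                                     skip = reason)
  assign_uri <- stats::setNames(list(), character(0))  # var -> uri
  assign_const <- list()                               # var -> character values
  start_key <- registry_key(inst$source_id, inst$entity, inst$local_id)

  locate_instance <- function(entity) {
    if (entity == inst$entity) inst
    else graph_find_entity(graph, start_key, entity)
  }
  ## referencing variables first (create() needs their tokens)
  for (vn in cls$referencing) {
    b <- binding$vars[[vn]]
    src <- locate_instance(b$entity)
    if (is.null(src))
      return(skip(paste0("no reachable instance of '", b$entity,
                         "' for variable ", vn)))
    key <- if (!is.null(b$class_uri %||% b$class))
      registry_key(src$source_id, src$entity, src$local_id,
                   b$class_uri %||% look(b$class, "class"))
    else registry_key(src$source_id, src$entity, src$local_id)
    uri <- registry[[key]]
    if (is.null(uri))
      return(skip(paste0("referenced individual missing for variable ", vn)))
    assign_uri[[vn]] <- uri
  }
  ## CONSTANT variables
  for (v in pattern$variables) {
    if (v$kind != "CONSTANT") next
    b <- binding$vars[[v$name]]
    if (is.null(b) || b$kind != "constant")
      return(skip(paste0("CONSTANT variable ", v$name, " unbound")))
    src <- locate_instance(b$entity)
    vals <- if (is.null(src)) character(0) else resolve_path(src, b$path)
    if (length(vals) == 0L)
      return(skip(paste0("CONSTANT path '", b$path, "' resolved to no values")))
    assign_const[[v$name]] <- vals
  }
  ## creating variables
  new_inds <- list()
  token_of <- function(uri) {
    t <- tokens[uri]
    if (is.na(t)) utils::URLdecode(uri_local_name(uri)) else unname(t)
  }
  context_token <- if (length(assign_uri)) token_of(assign_uri[[1]])
                   else inst$local_id
  for (vn in cls$creating) {
    v <- pattern_var(pattern, vn)
    cls_text <- creating_class_text(pattern, vn)
    if (is.na(cls_text))
      stop("classification error: creating variable ", vn, " is never typed")
    cls_uri <- look(cls_text, "class")
    token <- if (!is.null(v$generator)) {
      base_uri <- assign_uri[[v$generator$base_variable]]
      if (is.null(base_uri))
        return(skip(paste0("create() base ", v$generator$base_variable,
                           " unresolved")))
      paste0(token_of(base_uri), v$generator$suffix)
    } else paste0(context_token, "_", sub("^\\?", "", vn))
    uri <- mint_uri(policy, cls_uri, token)
    nd <- individual(uri, classes = cls_uri,
                     provenance = data.frame(source_id = inst$source_id,
                                             entity = inst$entity,
                                             local_id = inst$local_id,
                                             stringsAsFactors = FALSE))
    attr(nd, "token") <- token
    new_inds[[uri]] <- nd
    assign_uri[[vn]] <- uri
  }
  ## statements
  class_assert <- list()
  data_rows <- list(); obj_rows <- list()
  for (s in pattern$statements) {
    subj <- assign_uri[[s$var]]
    if (is.null(subj)) return(skip(paste0("subject variable ", s$var,
                                          " unresolved")))
    if (s$form == "instanceOf") {
      pe <- parse_class_expr_text(s$class_text)
      named <- vapply(pe$classes, function(cn) look(cn, "class"), character(1),
                      USE.NAMES = FALSE)
      for (cu in named)
        class_assert[[length(class_assert) + 1L]] <-
          list(subject = subj, class = cu)
      if (length(pe$restrictions)) {
        res_uris <- lapply(pe$restrictions, function(r)
          list(property = look(r$property, "oprop"),
               filler = look(r$filler, "class")))
        for (r in res_uris) {
          ftok <- paste0(token_of(subj), "_", uri_local_name(r$property))
          furi <- mint_uri(policy, r$filler, ftok)
          fi <- individual(furi, classes = r$filler,
                           provenance = data.frame(
                             source_id = inst$source_id, entity = inst$entity,
                             local_id = inst$local_id, stringsAsFactors = FALSE))
          attr(fi, "token") <- ftok
          new_inds[[furi]] <- fi
          obj_rows[[length(obj_rows) + 1L]] <-
            data.frame(subject = subj, property = r$property, object = furi,
                       external = FALSE, stringsAsFactors = FALSE)
        }
        class_assert[[length(class_assert) + 1L]] <-
          list(subject = subj,
               class = class_expr(named,
                                  lapply(res_uris, function(r)
                                    list(property = r$property,
                                         filler = r$filler))))
      }
    } else {
      if (s$object$type == "var" &&
          pattern_var(pattern, s$object$value)$kind == "INDIVIDUAL") {
        pu <- look(s$property, "oprop")
        obj <- assign_uri[[s$object$value]]
        if (is.null(obj)) return(skip(paste0("object variable ",
                                             s$object$value, " unresolved")))
        obj_rows[[length(obj_rows) + 1L]] <-
          data.frame(subject = subj, property = pu, object = obj,
                     external = FALSE, stringsAsFactors = FALSE)
      } else {
        pu <- look(s$property, "dprop")
        range <- onto$dprops[[pu]]$range
        if (is.na(range)) range <- xsd_uri("string")
        vals <- if (s$object$type == "var") assign_const[[s$object$value]]
                else s$object$value
        for (v in vals)
          data_rows[[length(data_rows) + 1L]] <-
            data.frame(subject = subj, property = pu, value = v,
                       datatype = range, stringsAsFactors = FALSE)
      }
    }
  }
  batch <- axiom_batch(
    individuals = unname(new_inds),
    class_assert = class_assert,
    data = if (length(data_rows)) do.call(rbind, data_rows) else NULL,
    objects = if (length(obj_rows)) do.call(rbind, obj_rows) else NULL)
  attr(batch, "assignments") <- assign_uri
  attr(batch, "tokens") <- stats::setNames(
    vapply(new_inds, function(x) attr(x, "token"), character(1)),
    vapply(new_inds, `[[`, character(1), "uri"))
  batch
}
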