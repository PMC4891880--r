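## schema_model: one uniform entity-attribute-relation view of an input
## source (XML Schema subset or relational/tabular), plus a uniform record
## model of its instance data.

#' Construct an input schema
#'
#' An input schema is the uniform entity-attribute-relation view of a data
#' source. XML Schemas and relational schemas are both reduced to this model
#' so that a single set of mapping rules applies to either kind.
#'
#' @param name schema name.
#' @param kind "xml" or "relational".
#' @param entities named list of [schema_entity()] objects.
#' @param relations named list of relations, each with fields `name`,
#'   `source`, `target`, `realization`.
#' @return object of class `input_schema`.
#' @export
input_schema <- function(name, kind = c("xml", "relational"),
                         entities = list(), relations = list()) {
  kind <- match.arg(kind)
  enames <- vapply(entities, `[[`, character(1), "name")
  if (anyDuplicated(enames))
    stop("duplicate entity name in schema: ",
         paste(unique(enames[duplicated(enames)]), collapse = ", "))
  names(entities) <- enames
  for (r in relations) {
    if (!r$source %in% enames || !r$target %in% enames)
      stop("relation '", r$name, "' references undeclared entity")
    ok <- switch(r$realization,
      "xml-containment" = kind == "xml",
      "foreign-key" = kind == "relational",
      "reference-attribute" = TRUE,
      FALSE)
    if (!ok)
      stop("relation '", r$name, "' realization '", r$realization,
           "' inconsistent with schema kind '", kind, "'")
  }
  if (length(relations))
    names(relations) <- vapply(relations, `[[`, character(1), "name")
  structure(list(name = name, kind = kind, entities = entities,
                 relations = relations),
            class = "input_schema")
}

#' Construct a schema entity
#' @param name entity name.
#' @param attributes list of attributes, each with fields `owner`, `path`,
#'   `value_kind` (one of text, integer, decimal, boolean).
#' @param key_attribute optional path of the identifying attribute.
#' @return object of class `schema_entity`.
#' @export
schema_entity <- function(name, attributes = list(), key_attribute = NULL) {
  paths <- vapply(attributes, `[[`, character(1), "path")
  if (anyDuplicated(paths))
    stop("duplicate attribute path in entity '", name, "'")
  if (length(attributes)) names(attributes) <- paths
  structure(list(name = name, attributes = attributes,
                 key_attribute = key_attribute),
            class = "schema_entity")
}

schema_attribute <- function(owner, path, value_kind = "text") {
  stopifnot(nzchar(path))
  list(owner = owner, path = path, value_kind = value_kind)
}

schema_relation <- function(name, source, target,
                            realization = c("xml-containment", "foreign-key",
                                            "reference-attribute")) {
  list(name = name, source = source, target = target,
       realization = match.arg(realization))
}

#' @export
print.input_schema <- function(x, ...) {
  cat("<input_schema> ", x$name, " (", x$kind, "): ",
      length(x$entities), " entities, ", length(x$relations),
      " relations\n", sep = "")
  invisible(x)
}

## ---- instance model -------------------------------------------------------

## A tree node mirrors one source record's structure: XML element (name,
## attributes, text, child nodes) or a tabular row (columns doubled as
## attributes and text-bearing children so both path styles resolve).
tree_node <- function(name, attrs = character(0), text = NA_character_,
                      children = list()) {
  list(name = name, attrs = attrs, text = text, children = children)
}

#' Construct a data instance
#'
#' One record of an input source: an occurrence of a schema entity carrying
#' its attribute values (as a structural tree resolvable with
#' [resolve_path()]) and its links to other records.
#'
#' @param entity entity name in the governing schema.
#' @param local_id identifier unique within (source, entity).
#' @param tree structural value tree of the record.
#' @param links list of links, each `list(relation=, target_entity=, target_local_id=)`.
#' @param source_id identifier of the originating resource.
#' @return object of class `data_instance`.
#' @export
data_instance <- function(entity, local_id, tree, links = list(),
                          source_id = "source") {
  structure(list(entity = entity, local_id = local_id, tree = tree,
                 links = links, source_id = source_id),
            class = "data_instance")
}

#' @export
print.data_instance <- function(x, ...) {
  cat("<data_instance> ", x$entity, "[", x$local_id, "] from ", x$source_id,
      ", ", length(x$links), " links\n", sep = "")
  invisible(x)
}

## ---- attribute path language ---------------------------------------------

## Steps separated by "/": "@name" (attribute of current node; final step
## only) or "child" with an optional single predicate [@attr="literal"].
parse_path <- function(path) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stop("path-syntax error: empty path")
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (any(!nzchar(parts))) stop("path-syntax error: empty step in '", path, "'")
  steps <- lapply(parts, function(p) {
    if (grepl("^@[A-Za-z_][A-Za-z0-9_.\\-]*$", p))
      return(list(kind = "attr", name = sub("^@", "", p)))
    m <- regmatches(p, regexec(
      "^([A-Za-z_][A-Za-z0-9_.\\-]*)(\\[@([A-Za-z_][A-Za-z0-9_.\\-]*)\\s*=\\s*\"([^\"]*)\"\\])?$",
      p))[[1]]
    if (length(m) == 0L) stop("path-syntax error: bad step '", p, "' in '", path, "'")
    list(kind = "child", name = m[2],
         pred_attr = if (nzchar(m[3])) m[4] else NULL,
         pred_val = if (nzchar(m[3])) m[5] else NULL)
  })
  nattr <- sum(vapply(steps, function(s) s$kind == "attr", logical(1)))
  if (nattr > 1L || (nattr == 1L && steps[[length(steps)]]$kind != "attr"))
    stop("path-syntax error: attribute step must be final in '", path, "'")
  steps
}

#' Resolve an attribute path against a data instance
#'
#' The path language expresses child steps, attribute steps (`@name`) and at
#' most one `[@attr="literal"]` predicate per step, e.g.
#' `property[@name="isChiral"]/val`. Absence of matches is an empty result,
#' never an error; only a syntactically invalid path raises.
#'
#' @param instance a [data_instance()].
#' @param path path expression.
#' @return character vector of matching values in document/row order
#'   (possibly empty).
#' @export
resolve_path <- function(instance, path) {
  steps <- parse_path(path)
  nodes <- list(instance$tree)
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (st$kind == "attr") {
      vals <- unlist(lapply(nodes, function(n) {
        v <- n$attrs[st$name]
        if (is.null(v) || is.na(v)) NULL else unname(v)
      }))
      return(as.character(vals %||% character(0)))
    }
    nodes <- unlist(lapply(nodes, function(n) {
      Filter(function(ch) {
        if (ch$name != st$name) return(FALSE)
        if (is.null(st$pred_attr)) return(TRUE)
        v <- ch$attrs[st$pred_attr]
        !is.null(v) && !is.na(v) && identical(unname(v), st$pred_val)
      }, n$children)
    }), recursive = FALSE)
    if (length(nodes) == 0L) return(character(0))
  }
  vals <- unlist(lapply(nodes, function(n)
    if (!is.na(n$text) && nzchar(n$text)) n$text else NULL))
  as.character(vals %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- XML Schema reader ----------------------------------------------------

XS <- "http://www.w3.org/2001/XMLSchema"

xsd_value_kind <- function(type) {
  ln <- sub("^[A-Za-z0-9_]+:", "", type)
  switch(ln,
    int = , integer = , long = , short = , nonNegativeInteger = ,
    positiveInteger = "integer",
    decimal = , double = , float = "decimal",
    boolean = "boolean",
    "text")
}

#' Load an XML Schema (subset) as an input schema
#'
#' Supports global/local element declarations, inline complex types with
#' sequences, attributes and simple types. Complex-typed elements become
#' entities; XML attributes and simple-typed child elements become
#' attributes; nesting between complex elements becomes containment
#' relations named `<parent>_<child>`. Imports, includes, redefinitions and
#' substitution groups are rejected with an unsupported-construct error.
#'
#' @param xsd_document XML Schema document text.
#' @return an [input_schema()] of kind "xml".
#' @export
load_xml_schema <- function(xsd_document) {
  doc <- tryCatch(xml2::read_xml(xsd_document),
                  error = function(e) stop("XSD parse error: ",
                                           conditionMessage(e), call. = FALSE))
  root <- xml2::xml_root(doc)
  if (xml_ns_strip_name(root) != "schema")
    stop("XSD parse error: root element is not xs:schema")
  for (bad in c("import", "include", "redefine", "group", "attributeGroup")) {
    if (length(xml2::xml_find_all(doc, paste0("//*[local-name()='", bad, "']"))))
      stop("unsupported-construct: xs:", bad)
  }
  if (length(xml2::xml_find_all(doc, "//*[@substitutionGroup]")))
    stop("unsupported-construct: substitutionGroup")

  entities <- list()
  relations <- list()

  walk_element <- function(el, parent_entity = NULL) {
    name <- xml2::xml_attr(el, "name")
    if (is.na(name)) stop("unsupported-construct: element reference (ref=)")
    ct <- xml2::xml_find_first(el, "./*[local-name()='complexType']")
    type_attr <- xml2::xml_attr(el, "type")
    if (inherits(ct, "xml_missing")) {
      ## simple-typed element: an attribute of the parent entity
      if (is.null(parent_entity))
        stop("unsupported-construct: global simple-typed element '", name, "'")
      return(list(kind = "attribute",
                  attr = schema_attribute(parent_entity, name,
                                          xsd_value_kind(type_attr %||% "string"))))
    }
    ## complex-typed element: an entity
    attrs <- list()
    child_entities <- character(0)
    for (a in xml2::xml_find_all(ct, "./*[local-name()='attribute']")) {
      an <- xml2::xml_attr(a, "name")
      at <- xml2::xml_attr(a, "type")
      attrs[[length(attrs) + 1L]] <-
        schema_attribute(name, paste0("@", an),
                         xsd_value_kind(if (is.na(at)) "string" else at))
    }
    seq_el <- xml2::xml_find_first(ct, "./*[local-name()='sequence']")
    if (!inherits(seq_el, "xml_missing")) {
      for (ch in xml2::xml_find_all(seq_el, "./*[local-name()='element']")) {
        res <- walk_element(ch, parent_entity = name)
        if (res$kind == "attribute")
          attrs[[length(attrs) + 1L]] <- res$attr
        else
          child_entities <- c(child_entities, res$name)
      }
    }
    if (!is.null(entities[[name]]))
      stop("duplicate entity declaration for '", name, "' in XSD")
    entities[[name]] <<- schema_entity(name, attrs)
    for (ce in child_entities) {
      rn <- paste0(name, "_", ce)
      relations[[rn]] <<- schema_relation(rn, name, ce, "xml-containment")
    }
    list(kind = "entity", name = name)
  }

  globals <- xml2::xml_find_all(root, "./*[local-name()='element']")
  if (length(globals) == 0L)
    stop("XSD parse error: no global element declaration")
  for (g in globals) walk_element(g)
  input_schema(name = xml2::xml_attr(root, "targetNamespace") %|na|% "xml-schema",
               kind = "xml", entities = entities, relations = relations)
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

## xml2 dropped xml_ns_strip_name in some versions; local shim.
xml_ns_strip_name <- function(node) sub("^.*:", "", xml2::xml_name(node))

## ---- relational schema reader ---------------------------------------------

sql_value_kind <- function(type) {
  t <- toupper(sub("\\(.*$", "", trimws(type)))
  if (t %in% c("INT", "INTEGER", "BIGINT", "SMALLINT")) "integer"
  else if (t %in% c("FLOAT", "REAL", "DOUBLE", "DECIMAL", "NUMERIC")) "decimal"
  else if (t %in% c("BOOL", "BOOLEAN")) "boolean"
  else "text"
}

## split on commas at parenthesis depth 0
split_top <- function(s) {
  out <- character(0); depth <- 0L; cur <- ""
  for (ch in strsplit(s, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) { out <- c(out, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

#' Load a relational schema as an input schema
#'
#' Accepts either DDL text (a `CREATE TABLE` subset with typed columns,
#' `PRIMARY KEY` and `FOREIGN KEY ... REFERENCES` clauses) or a YAML table
#' descriptor with keys `tables: [{name, columns: [{name, kind}],
#' primary_key, foreign_keys: [{column, references}]}]`. Tables become
#' entities, columns attributes, foreign keys relations named
#' `<table>_<column>`. A composite primary key leaves `key_attribute` unset
#' with a recorded warning; identity must then come from identity rules.
#'
#' @param descriptor DDL or YAML text.
#' @return an [input_schema()] of kind "relational".
#' @export
load_tabular_schema <- function(descriptor) {
  if (grepl("CREATE\\s+TABLE", descriptor, ignore.case = TRUE))
    load_ddl_schema(descriptor)
  else
    load_yaml_schema(descriptor)
}

load_ddl_schema <- function(ddl) {
  warnings <- character(0)
  stmts <- strsplit(ddl, ";")[[1]]
  entities <- list(); relations <- list()
  for (st in stmts) {
    st <- trimws(st)
    if (!nzchar(st)) next
    m <- regmatches(st, regexec(
      "(?is)^CREATE\\s+TABLE\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*\\((.*)\\)\\s*$",
      st, perl = TRUE))[[1]]
    if (length(m) == 0L) stop("DDL parse error near: ", substr(st, 1, 40))
    tname <- m[2]
    attrs <- list(); key <- NULL; composite <- FALSE
    for (item in trimws(split_top(m[3]))) {
      if (grepl("^PRIMARY\\s+KEY", item, ignore.case = TRUE)) {
        cols <- trimws(strsplit(gsub("^.*\\(|\\).*$", "", item), ",")[[1]])
        if (length(cols) > 1L) {
          composite <- TRUE
          warnings <- c(warnings, paste0(
            "composite primary key on table '", tname,
            "': no key_attribute recorded; identity rules must identify rows"))
        } else key <- cols
      } else if (grepl("^FOREIGN\\s+KEY", item, ignore.case = TRUE)) {
        fm <- regmatches(item, regexec(
          "(?i)^FOREIGN\\s+KEY\\s*\\(\\s*([A-Za-z0-9_]+)\\s*\\)\\s*REFERENCES\\s+([A-Za-z0-9_]+)",
          item, perl = TRUE))[[1]]
        if (length(fm) == 0L) stop("DDL parse error in foreign key: ", item)
        rn <- paste0(tname, "_", fm[2])
        relations[[rn]] <- list(name = rn, source = tname, target = fm[3],
                                column = fm[2], realization = "foreign-key")
      } else {
        cm <- regmatches(item, regexec(
          "^([A-Za-z_][A-Za-z0-9_]*)\\s+([A-Za-z]+(\\([0-9, ]*\\))?)(.*)$",
          item))[[1]]
        if (length(cm) == 0L) stop("DDL parse error in column: ", item)
        attrs[[length(attrs) + 1L]] <-
          schema_attribute(tname, cm[2], sql_value_kind(cm[3]))
        if (grepl("PRIMARY\\s+KEY", cm[5], ignore.case = TRUE)) key <- cm[2]
      }
    }
    entities[[tname]] <- schema_entity(tname, attrs,
                                       key_attribute = if (composite) NULL else key)
  }
  for (r in relations)
    if (is.null(entities[[r$target]]))
      stop("dangling-reference: foreign key in '", r$source,
           "' references undeclared table '", r$target, "'")
  sch <- input_schema("relational-schema", "relational", entities,
                      lapply(relations, function(r)
                        schema_relation(r$name, r$source, r$target, "foreign-key")))
  ## keep FK column bookkeeping for the instance reader
  attr(sch, "fk_columns") <- lapply(relations, function(r)
    list(table = r$source, column = r$column, references = r$target))
  attr(sch, "warnings") <- warnings
  for (w in warnings) warning(w, call. = FALSE)
  sch
}

load_yaml_schema <- function(text) {
  y <- yaml::yaml.load(text)
  if (is.null(y$tables)) stop("descriptor parse error: no 'tables' key")
  warnings <- character(0)
  entities <- list(); relations <- list(); fks <- list()
  for (tb in y$tables) {
    attrs <- lapply(tb$columns, function(cc)
      schema_attribute(tb$name, cc$name, cc$kind %||% "text"))
    key <- tb$primary_key
    if (length(key) > 1L) {
      warnings <- c(warnings, paste0("composite primary key on table '",
                                     tb$name, "'"))
      key <- NULL
    }
    entities[[tb$name]] <- schema_entity(tb$name, attrs, key_attribute = key)
    for (fk in tb$foreign_keys) {
      rn <- paste0(tb$name, "_", fk$column)
      relations[[rn]] <- schema_relation(rn, tb$name, fk$references, "foreign-key")
      fks[[rn]] <- list(table = tb$name, column = fk$column,
                        references = fk$references)
    }
  }
  for (r in relations)
    if (is.null(entities[[r$target]]))
      stop("dangling-reference: foreign key references undeclared table '",
           r$target, "'")
  sch <- input_schema("relational-schema", "relational", entities, relations)
  attr(sch, "fk_columns") <- fks
  attr(sch, "warnings") <- warnings
  for (w in warnings) warning(w, call. = FALSE)
  sch
}

## ---- instance readers ------------------------------------------------------

xml_to_tree <- function(node) {
  kids <- xml2::xml_children(node)
  txt <- if (length(kids) == 0L) trimws(xml2::xml_text(node)) else NA_character_
  tree_node(name = xml_ns_strip_name(node),
            attrs = unlist(as.list(xml2::xml_attrs(node))) %||% character(0),
            text = if (!is.na(txt) && nzchar(txt)) txt else NA_character_,
            children = lapply(kids, xml_to_tree))
}

#' Read XML instance documents into data instances
#'
#' Emits one [data_instance()] per occurrence of each entity element, in
#' document order (parents before their contained children), with
#' containment links populated. The local id is the entity's key attribute
#' value when declared, otherwise an entity-prefixed document-order ordinal.
#'
#' @param xml_document XML text conforming to the schema subset.
#' @param schema the governing [input_schema()].
#' @param source_id identifier recorded as each instance's provenance.
#' @param strict if TRUE an undeclared element is an error; if FALSE it is
#'   skipped and noted in the `read_log` attribute of the result.
#' @return list of [data_instance()] with attribute `read_log`.
#' @export
read_xml_instances <- function(xml_document, schema, source_id = "source",
                               strict = TRUE) {
  doc <- xml2::read_xml(xml_document)
  out <- list(); rlog <- character(0)
  counters <- new.env(parent = emptyenv())
  next_ord <- function(entity) {
    n <- (get0(entity, envir = counters) %||% 0L) + 1L
    assign(entity, n, envir = counters)
    paste0(entity, "_", n)
  }
  walk <- function(node, parent_entity = NULL) {
    nm <- xml_ns_strip_name(node)
    ent <- schema$entities[[nm]]
    if (is.null(ent)) {
      ## not an entity: acceptable if it is an attribute of the parent
      if (!is.null(parent_entity) &&
          nm %in% names(schema$entities[[parent_entity]]$attributes))
        return(NULL)
      if (strict)
        stop("undeclared element '", nm, "' (strict mode)")
      rlog <<- c(rlog, paste0("skipped undeclared element '", nm, "'"))
      return(NULL)
    }
    tree <- xml_to_tree(node)
    lid <- NULL
    if (!is.null(ent$key_attribute)) {
      kv <- resolve_path(data_instance(nm, "", tree), ent$key_attribute)
      if (length(kv)) lid <- kv[[1]]
    }
    if (is.null(lid)) lid <- next_ord(nm)
    idx <- length(out) + 1L
    out[[idx]] <<- data_instance(nm, lid, tree, links = list(),
                                 source_id = source_id)
    ## children in document order, collecting containment links
    links <- list()
    for (ch in xml2::xml_children(node)) {
      clid <- walk(ch, parent_entity = nm)
      if (!is.null(clid)) {
        rel <- paste0(nm, "_", clid$entity)
        if (!is.null(schema$relations[[rel]]))
          links[[length(links) + 1L]] <-
            list(relation = rel, target_entity = clid$entity,
                 target_local_id = clid$local_id)
      }
    }
    out[[idx]]$links <<- links
    list(entity = nm, local_id = lid)
  }
  root <- xml2::xml_root(doc)
  if (!is.null(schema$entities[[xml_ns_strip_name(root)]])) {
    walk(root)
  } else {
    for (ch in xml2::xml_children(root)) walk(ch)
  }
  attr(out, "read_log") <- rlog
  out
}

row_tree <- function(entity, vals) {
  present <- !is.na(vals) & nzchar(vals)
  tree_node(entity, attrs = vals[present],
            children = unname(lapply(names(vals)[present], function(cn)
              tree_node(cn, text = vals[[cn]]))))
}

#' Read tabular rows into data instances
#'
#' One instance per row; foreign-key columns produce links; empty cells
#' (NA or "") produce absent attribute values, never empty-text literals.
#'
#' @param rows named list of data frames, one per table.
#' @param schema the governing relational [input_schema()].
#' @param source_id provenance identifier.
#' @param strict if TRUE, a value violating its declared kind or a
#'   duplicated primary key is an error; if FALSE offending rows are dropped
#'   with a note in the `read_log` attribute.
#' @return list of [data_instance()] with attribute `read_log`.
#' @export
read_tabular_instances <- function(rows, schema, source_id = "source",
                                   strict = TRUE) {
  fks <- attr(schema, "fk_columns") %||% list()
  out <- list(); rlog <- character(0)
  for (ename in names(schema$entities)) {
    df <- rows[[ename]]
    if (is.null(df)) next
    ent <- schema$entities[[ename]]
    unknown <- setdiff(names(df), names(ent$attributes))
    if (length(unknown)) {
      msg <- paste0("unknown column(s) in table '", ename, "': ",
                    paste(unknown, collapse = ", "))
      if (strict) stop(msg) else { rlog <- c(rlog, msg); df <- df[setdiff(names(df), unknown)] }
    }
    efks <- Filter(function(f) f$table == ename, fks)
    seen_keys <- character(0)
    for (i in seq_len(nrow(df))) {
      vals <- vapply(names(df), function(cn) {
        v <- df[[cn]][i]
        if (is.na(v)) NA_character_ else as.character(v)
      }, character(1))
      ## value-kind check
      bad <- FALSE
      for (cn in names(vals)) {
        v <- vals[[cn]]
        if (is.na(v) || !nzchar(v)) next
        kind <- ent$attributes[[cn]]$value_kind
        if (!kind_ok(v, kind)) {
          msg <- paste0("coercion error in table '", ename, "' row ", i,
                        " column '", cn, "': '", v, "' is not ", kind)
          if (strict) stop(msg)
          rlog <- c(rlog, msg); bad <- TRUE; break
        }
      }
      if (bad) next
      lid <- NULL
      if (!is.null(ent$key_attribute)) {
        kv <- vals[[ent$key_attribute]]
        if (!is.null(kv) && !is.na(kv) && nzchar(kv)) lid <- kv
      }
      if (is.null(lid)) lid <- paste0(ename, "_", i)
      if (!is.null(ent$key_attribute)) {
        if (lid %in% seen_keys) {
          msg <- paste0("duplicate primary key '", lid, "' in table '",
                        ename, "' row ", i)
          if (strict) stop(msg)
          rlog <- c(rlog, msg); next
        }
        seen_keys <- c(seen_keys, lid)
      }
      links <- list()
      for (fk in efks) {
        v <- vals[[fk$column]]
        if (!is.null(v) && !is.na(v) && nzchar(v))
          links[[length(links) + 1L]] <-
            list(relation = paste0(ename, "_", fk$column),
                 target_entity = fk$references, target_local_id = v)
      }
      out[[length(out) + 1L]] <-
        data_instance(ename, lid, row_tree(ename, vals), links, source_id)
    }
  }
  attr(out, "read_log") <- rlog
  out
}
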