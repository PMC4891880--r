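## mapping_rules: the three basic rule types (entity, attribute, relation)
## with optional value conditions, identity-rule and pattern-binding
## declarations, parsed from a small declarative text dialect.
##
## Dialect (one block per non-indented line; indented lines are options;
## '#' starts a comment):
##
##   prefix orth <http://purl.org/net/orth#>
##
##   entity gene -> orth:Gene
##     token @geneId
##     when @geneId eq "pyc-1"          # optional condition
##
##   attribute gene/@geneId -> orth:Gene orth:Identifier
##
##   relation database database_gene gene -> sio:database orth:contains orth:Gene
##
##   link gene -> <http://purl.uniprot.org/uniprot/>
##     token @protId
##     class orth:Protein
##
##   identity orth:Gene
##     properties orth:Identifier, ro:in_taxon
##     behaviour merge                  # or: link
##     merged-uri first-wins            # or: fresh-prefix
##     prefix <http://example.org/merged/>
##
##   bind gene_links
##     var ?gene = gene : orth:Gene
##     var ?taxon = species : ncbi:organisms
##     constant ?c = record/@alt_code
##     when property[@name="isChiral"]/val eq "1"

#' Construct a condition over an attribute path
#' @param attribute_path path expression (see [resolve_path()]).
#' @param comparator one of eq, ne, lt, le, gt, ge. Ordering comparators
#'   require a numeric value kind.
#' @param literal comparison literal (lexical form).
#' @param value_kind "text", "integer", "decimal" or "boolean".
#' @return object of class `rule_condition`.
#' @export
rule_condition <- function(attribute_path, comparator, literal,
                           value_kind = "text") {
  comparator <- match.arg(comparator, c("eq", "ne", "lt", "le", "gt", "ge"))
  if (comparator %in% c("lt", "le", "gt", "ge") &&
      !value_kind %in% c("integer", "decimal"))
    stop("ordering comparator '", comparator, "' requires a numeric value kind")
  parse_path(attribute_path)  # syntax check
  structure(list(attribute_path = attribute_path, comparator = comparator,
                 literal = literal, value_kind = value_kind),
            class = "rule_condition")
}

#' Evaluate a condition against a data instance
#'
#' Existential semantics over multi-valued paths: TRUE iff any resolved
#' value satisfies the comparator after value-kind coercion. An empty
#' resolution is FALSE. A coercion failure counts as a non-match and is
#' recorded in the `warnings` attribute of the result.
#'
#' @param cond a [rule_condition()].
#' @param instance a [data_instance()].
#' @return logical scalar, with attribute `warnings` (character).
#' @export
evaluate_condition <- function(cond, instance) {
  vals <- resolve_path(instance, cond$attribute_path)
  warns <- character(0)
  if (length(vals) == 0L)
    return(structure(FALSE, warnings = warns))
  hit <- FALSE
  for (v in vals) {
    if (cond$value_kind %in% c("integer", "decimal")) {
      a <- suppressWarnings(as.numeric(v))
      b <- suppressWarnings(as.numeric(cond$literal))
      if (is.na(a) || is.na(b)) {
        warns <- c(warns, paste0("coercion failure comparing '", v, "' as ",
                                 cond$value_kind))
        next
      }
      ok <- switch(cond$comparator, eq = a == b, ne = a != b, lt = a < b,
                   le = a <= b, gt = a > b, ge = a >= b)
    } else {
      ok <- switch(cond$comparator,
                   eq = identical(v, cond$literal),
                   ne = !identical(v, cond$literal),
                   { warns <- c(warns, "ordering comparator on text value")
                     FALSE })
    }
    if (isTRUE(ok)) { hit <- TRUE; break }
  }
  structure(hit, warnings = warns)
}

#' Construct a mapping rule set
#' @param entity_rules,attribute_rules,relation_rules,identity_rules,
#'   pattern_bindings,external_links rule lists (see [parse_mapping_document()]).
#' @param prefixes named character vector of prefix bindings local to the
#'   mapping document.
#' @return object of class `mapping_rule_set`.
#' @export
mapping_rule_set <- function(entity_rules = list(), attribute_rules = list(),
                             relation_rules = list(), identity_rules = list(),
                             pattern_bindings = list(),
                             external_links = list(),
                             prefixes = character(0)) {
  ids <- vapply(entity_rules, function(r) r$id %||% "", character(1))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids))
    stop("duplicate rule identifier: ", ids[duplicated(ids)][1])
  structure(list(entity_rules = entity_rules,
                 attribute_rules = attribute_rules,
                 relation_rules = relation_rules,
                 identity_rules = identity_rules,
                 pattern_bindings = pattern_bindings,
                 external_links = external_links,
                 prefixes = prefixes),
            class = "mapping_rule_set")
}

#' @export
print.mapping_rule_set <- function(x, ...) {
  cat("<mapping_rule_set> ", length(x$entity_rules), " entity, ",
      length(x$attribute_rules), " attribute, ", length(x$relation_rules),
      " relation rules; ", length(x$identity_rules), " identity rules; ",
      length(x$pattern_bindings), " pattern bindings\n", sep = "")
  invisible(x)
}

## ---- dialect parser --------------------------------------------------------

strip_comment <- function(line) {
  ## '#' outside quotes starts a comment, but only at line start or after
  ## whitespace (so URI fragments like <...#> survive)
  chars <- strsplit(line, "")[[1]]
  inq <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == "\"") inq <- !inq
    if (chars[i] == "#" && !inq &&
        (i == 1L || grepl("^\\s$", chars[i - 1L])))
      return(substr(line, 1L, i - 1L))
  }
  line
}

## split on whitespace outside quotes / brackets
split_fields <- function(s) {
  out <- character(0); cur <- ""; inq <- FALSE; depth <- 0L
  for (ch in strsplit(s, "")[[1]]) {
    if (ch == "\"") inq <- !inq
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") depth <- depth - 1L
    if (grepl("^\\s$", ch) && !inq && depth == 0L) {
      if (nzchar(cur)) { out <- c(out, cur); cur <- "" }
    } else cur <- paste0(cur, ch)
  }
  if (nzchar(cur)) out <- c(out, cur)
  out
}

parse_literal_token <- function(tok, comparator) {
  if (grepl("^\".*\"$", tok)) {
    kind <- if (comparator %in% c("lt", "le", "gt", "ge")) "decimal" else "text"
    list(literal = substr(tok, 2L, nchar(tok) - 1L), kind = kind)
  } else if (grepl("^[+-]?[0-9]+$", tok)) {
    list(literal = tok, kind = "integer")
  } else if (grepl("^[+-]?[0-9]*\\.[0-9]+$", tok)) {
    list(literal = tok, kind = "decimal")
  } else stop("bad literal token '", tok, "'")
}

parse_when <- function(fields, lineno) {
  if (length(fields) != 3L)
    stop("mapping syntax error at line ", lineno,
         ": expected 'when <path> <cmp> <literal>'")
  lit <- parse_literal_token(fields[3], fields[2])
  kind <- if (fields[2] %in% c("lt", "le", "gt", "ge") && lit$kind == "text")
    stop("mapping syntax error at line ", lineno,
         ": ordering comparator needs a numeric literal")
  else lit$kind
  rule_condition(fields[1], fields[2], lit$literal, kind)
}

strip_angle <- function(x) sub("^<", "", sub(">$", "", x))

#' Parse a mapping document
#'
#' Materializes all declared rules; unresolved ontology/schema names are
#' deferred to [validate_mapping()]. Syntax errors name the offending line.
#'
#' @param document mapping dialect text.
#' @return a [mapping_rule_set()].
#' @export
parse_mapping_document <- function(document) {
  raw <- strsplit(document, "\n", fixed = TRUE)[[1]]
  prefixes <- character(0)
  ers <- list(); ars <- list(); rrs <- list(); irs <- list()
  binds <- list(); links <- list()
  cur <- NULL   # current open block: list(type=, data=, line=)

  close_block <- function() {
    if (is.null(cur)) return(invisible())
    b <- cur; cur <<- NULL
    switch(b$type,
      entity = { ers[[length(ers) + 1L]] <<- b$data },
      link = { links[[length(links) + 1L]] <<- b$data },
      identity = {
        if (length(b$data$properties) == 0L)
          stop("mapping syntax error at line ", b$line,
               ": identity rule needs a 'properties' option")
        irs[[length(irs) + 1L]] <<- b$data
      },
      bind = { binds[[length(binds) + 1L]] <<- b$data })
  }

  for (ln in seq_along(raw)) {
    line <- strip_comment(raw[ln])
    if (!nzchar(trimws(line))) next
    indented <- grepl("^\\s", line)
    f <- split_fields(trimws(line))
    if (!indented) {
      close_block()
      head <- f[1]
      if (head == "prefix") {
        if (length(f) != 3L) stop("mapping syntax error at line ", ln)
        prefixes[f[2]] <- strip_angle(f[3])
      } else if (head == "entity") {
        if (length(f) != 4L || f[3] != "->")
          stop("mapping syntax error at line ", ln,
               ": expected 'entity <name> -> <Class>'")
        cur <- list(type = "entity", line = ln,
                    data = list(id = NULL, source_entity = f[2],
                                target_class = f[4], condition = NULL,
                                uri_token_path = NULL))
      } else if (head == "attribute") {
        if (length(f) != 5L || f[3] != "->")
          stop("mapping syntax error at line ", ln,
               ": expected 'attribute <entity>/<path> -> <Class> <Property>'")
        src <- f[2]
        slash <- regexpr("/", src, fixed = TRUE)
        if (slash < 0L)
          stop("mapping syntax error at line ", ln,
               ": attribute source must be <entity>/<path>")
        ars[[length(ars) + 1L]] <- list(
          source_entity = substr(src, 1L, slash - 1L),
          path = substring(src, slash + 1L),
          target_class = f[4], target_property = f[5])
      } else if (head == "relation") {
        if (length(f) != 8L || f[5] != "->")
          stop("mapping syntax error at line ", ln,
               ": expected 'relation <S1> <R1> <S2> -> <T1> <R2> <T2>'")
        rrs[[length(rrs) + 1L]] <- list(s1 = f[2], r1 = f[3], s2 = f[4],
                                        t1 = f[6], r2 = f[7], t2 = f[8])
      } else if (head == "identity") {
        if (length(f) != 2L)
          stop("mapping syntax error at line ", ln,
               ": expected 'identity <Class>'")
        cur <- list(type = "identity", line = ln,
                    data = list(target_class = f[2], properties = character(0),
                                behaviour = "merge",
                                merged_uri_policy = "first-wins",
                                fresh_prefix = NULL))
      } else if (head == "bind") {
        if (length(f) != 2L)
          stop("mapping syntax error at line ", ln,
               ": expected 'bind <pattern-name>'")
        cur <- list(type = "bind", line = ln,
                    data = list(pattern = f[2], vars = list(), condition = NULL))
      } else if (head == "link") {
        if (length(f) != 4L || f[3] != "->")
          stop("mapping syntax error at line ", ln,
               ": expected 'link <entity> -> <uri-base>'")
        cur <- list(type = "link", line = ln,
                    data = list(entity = f[2], base = strip_angle(f[4]),
                                token_path = NULL, class = NULL))
      } else stop("mapping syntax error at line ", ln,
                  ": unknown directive '", head, "'")
    } else {
      if (is.null(cur))
        stop("mapping syntax error at line ", ln, ": option outside a block")
      key <- f[1]
      if (cur$type == "entity") {
        if (key == "token") cur$data$uri_token_path <- f[2]
        else if (key == "when") cur$data$condition <- parse_when(f[-1], ln)
        else if (key == "id") cur$data$id <- f[2]
        else stop("mapping syntax error at line ", ln,
                  ": unknown entity option '", key, "'")
      } else if (cur$type == "identity") {
        if (key == "properties")
          cur$data$properties <- sub(",$", "", f[-1])
        else if (key == "behaviour") {
          if (!f[2] %in% c("merge", "link"))
            stop("mapping syntax error at line ", ln,
                 ": behaviour must be merge or link")
          cur$data$behaviour <- f[2]
        } else if (key == "merged-uri") {
          if (!f[2] %in% c("first-wins", "fresh-prefix"))
            stop("mapping syntax error at line ", ln,
                 ": merged-uri must be first-wins or fresh-prefix")
          cur$data$merged_uri_policy <- f[2]
        } else if (key == "prefix") cur$data$fresh_prefix <- strip_angle(f[2])
        else stop("mapping syntax error at line ", ln,
                  ": unknown identity option '", key, "'")
      } else if (cur$type == "bind") {
        if (key == "var") {
          ## var ?name = entity [: Class]
          if (length(f) < 4L || f[3] != "=" || !startsWith(f[2], "?"))
            stop("mapping syntax error at line ", ln,
                 ": expected 'var ?name = <entity> [: <Class>]'")
          cls <- if (length(f) >= 6L && f[5] == ":") f[6] else NULL
          cur$data$vars[[f[2]]] <- list(kind = "individual", entity = f[4],
                                        class = cls)
        } else if (key == "constant") {
          if (length(f) != 4L || f[3] != "=" || !startsWith(f[2], "?"))
            stop("mapping syntax error at line ", ln,
                 ": expected 'constant ?name = <entity>/<path>'")
          src <- f[4]
          slash <- regexpr("/", src, fixed = TRUE)
          if (slash < 0L)
            stop("mapping syntax error at line ", ln,
                 ": constant source must be <entity>/<path>")
          cur$data$vars[[f[2]]] <- list(kind = "constant",
                                        entity = substr(src, 1L, slash - 1L),
                                        path = substring(src, slash + 1L))
        } else if (key == "when") cur$data$condition <- parse_when(f[-1], ln)
        else stop("mapping syntax error at line ", ln,
                  ": unknown bind option '", key, "'")
      } else if (cur$type == "link") {
        if (key == "token") cur$data$token_path <- f[2]
        else if (key == "class") cur$data$class <- f[2]
        else stop("mapping syntax error at line ", ln,
                  ": unknown link option '", key, "'")
      }
    }
  }
  close_block()
  mapping_rule_set(ers, ars, rrs, irs, binds, links, prefixes)
}

## ---- validation ------------------------------------------------------------

#' Validate a mapping rule set against a schema and an ontology
#'
#' Reports unknown schema entities/attributes/relations, unknown ontology
#' classes/properties, attribute rules whose target is not a datatype
#' property, relation rules missing their entity rules, and condition
#' comparator/value-kind mismatches. An empty report is required before
#' [transform()] will run.
#'
#' @param rules a [mapping_rule_set()].
#' @param schema an [input_schema()].
#' @param onto an [ontology_model()].
#' @param patterns optional named list of [parse_pattern()] results, so
#'   pattern bindings can be checked too.
#' @return data.frame(kind, detail); zero rows iff valid.
#' @export
validate_mapping <- function(rules, schema, onto, patterns = NULL) {
  px <- rules$prefixes
  out <- list()
  add <- function(kind, detail)
    out[[length(out) + 1L]] <<- data.frame(kind = kind, detail = detail,
                                           stringsAsFactors = FALSE)
  look <- function(name, kind) onto_lookup(onto, name, kind, px)
  check_entity <- function(e, ctx) {
    if (is.null(schema$entities[[e]]))
      add("unknown-entity", paste0(ctx, ": entity '", e, "' not in schema"))
  }
  has_entity_rule <- function(S, Tc) {
    any(vapply(rules$entity_rules, function(r)
      r$source_entity == S && identical(look(r$target_class, "class"),
                                        look(Tc, "class")),
      logical(1)))
  }
  for (r in rules$entity_rules) {
    check_entity(r$source_entity, "entity rule")
    if (is.na(look(r$target_class, "class")))
      add("unknown-class", paste0("entity rule: class '", r$target_class, "'"))
    if (!is.null(r$condition)) {
      ok <- tryCatch({ parse_path(r$condition$attribute_path); TRUE },
                     error = function(e) FALSE)
      if (!ok) add("bad-path", paste0("condition path '",
                                      r$condition$attribute_path, "'"))
    }
  }
  for (r in rules$attribute_rules) {
    check_entity(r$source_entity, "attribute rule")
    tc <- look(r$target_class, "class")
    if (is.na(tc))
      add("unknown-class", paste0("attribute rule: class '", r$target_class, "'"))
    tp <- look(r$target_property, "property")
    if (is.na(tp))
      add("unknown-property", paste0("attribute rule: property '",
                                     r$target_property, "'"))
    else if (is.na(look(r$target_property, "dprop")))
      add("not-a-datatype-property",
          paste0("attribute rule target '", r$target_property,
                 "' is not a datatype property"))
    ok <- tryCatch({ parse_path(r$path); TRUE }, error = function(e) FALSE)
    if (!ok) add("bad-path", paste0("attribute rule path '", r$path, "'"))
    else if (!grepl("/", r$path, fixed = TRUE) &&
             !is.null(schema$entities[[r$source_entity]]) &&
             ## tabular columns resolve both as "col" and "@col"
             !r$path %in% names(schema$entities[[r$source_entity]]$attributes) &&
             !sub("^@", "", r$path) %in%
               names(schema$entities[[r$source_entity]]$attributes))
      add("unknown-attribute", paste0("attribute rule path '", r$path,
                                      "' not declared on entity '",
                                      r$source_entity, "'"))
    if (!is.na(tc) && !has_entity_rule(r$source_entity, r$target_class))
      add("missing-entity-rule",
          paste0("attribute rule for (", r$source_entity, ", ",
                 r$target_class, ") has no entity rule"))
  }
  for (r in rules$relation_rules) {
    check_entity(r$s1, "relation rule"); check_entity(r$s2, "relation rule")
    rel <- schema$relations[[r$r1]]
    if (is.null(rel))
      add("unknown-relation", paste0("relation rule: relation '", r$r1,
                                     "' not in schema"))
    else if (!setequal(c(rel$source, rel$target), c(r$s1, r$s2)))
      add("unknown-relation", paste0("relation '", r$r1,
                                     "' does not connect ", r$s1, " and ", r$s2))
    if (is.na(look(r$r2, "oprop")))
      add("not-an-object-property",
          paste0("relation rule target '", r$r2, "' is not an object property"))
    for (Tc in c(r$t1, r$t2))
      if (is.na(look(Tc, "class")))
        add("unknown-class", paste0("relation rule: class '", Tc, "'"))
    if (!is.na(look(r$t1, "class")) && !has_entity_rule(r$s1, r$t1))
      add("missing-entity-rule",
          paste0("relation rule needs entity rule for (", r$s1, ", ", r$t1, ")"))
    if (!is.na(look(r$t2, "class")) && !has_entity_rule(r$s2, r$t2))
      add("missing-entity-rule",
          paste0("relation rule needs entity rule for (", r$s2, ", ", r$t2, ")"))
  }
  for (r in rules$identity_rules) {
    if (is.na(look(r$target_class, "class")))
      add("unknown-class", paste0("identity rule: class '", r$target_class, "'"))
    for (p in r$properties)
      if (is.na(look(p, "property")))
        add("unknown-property", paste0("identity rule property '", p, "'"))
    if (r$merged_uri_policy == "fresh-prefix" && is.null(r$fresh_prefix))
      add("missing-prefix", paste0("identity rule for '", r$target_class,
                                   "' uses fresh-prefix without a prefix"))
  }
  for (b in rules$pattern_bindings) {
    for (vn in names(b$vars)) {
      v <- b$vars[[vn]]
      check_entity(v$entity, paste0("binding ", b$pattern))
      if (v$kind == "individual" && !is.null(v$class) &&
          is.na(look(v$class, "class")))
        add("unknown-class", paste0("binding ", b$pattern, ": class '",
                                    v$class, "'"))
    }
    if (!is.null(patterns)) {
      pat <- patterns[[b$pattern]]
      if (is.null(pat))
        add("unknown-pattern", paste0("binding references pattern '",
                                      b$pattern, "'"))
      else {
        declared <- vapply(pat$variables, `[[`, character(1), "name")
        for (vn in names(b$vars))
          if (!vn %in% declared)
            add("unknown-variable", paste0("binding ", b$pattern,
                                           ": variable ", vn, " not in pattern"))
        for (pv in pat$variables)
          if (pv$kind == "CONSTANT" &&
              (is.null(b$vars[[pv$name]]) ||
               b$vars[[pv$name]]$kind != "constant"))
            add("unbound-constant", paste0("binding ", b$pattern,
                                           ": CONSTANT ", pv$name,
                                           " must be bound to a path"))
      }
    }
  }
  for (l in rules$external_links) {
    check_entity(l$entity, "external link")
    if (!is_absolute_http(l$base))
      add("bad-uri", paste0("external link base '", l$base, "'"))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(kind = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

## Resolve all raw names in a validated rule set to URIs.
resolve_mapping <- function(rules, onto) {
  px <- rules$prefixes
  look <- function(name, kind) {
    u <- onto_lookup(onto, name, kind, px)
    if (is.na(u)) stop("unresolved name '", name, "' (", kind, ")")
    u
  }
  rules$entity_rules <- lapply(rules$entity_rules, function(r) {
    r$class_uri <- look(r$target_class, "class"); r
  })
  rules$attribute_rules <- lapply(rules$attribute_rules, function(r) {
    r$class_uri <- look(r$target_class, "class")
    r$property_uri <- look(r$target_property, "dprop")
    r
  })
  rules$relation_rules <- lapply(rules$relation_rules, function(r) {
    r$t1_uri <- look(r$t1, "class"); r$t2_uri <- look(r$t2, "class")
    r$r2_uri <- look(r$r2, "oprop")
    r
  })
  rules$identity_rules <- lapply(rules$identity_rules, function(r) {
    if (inherits(r, "identity_rule")) return(r)
    identity_rule(
      target_class = look(r$target_class, "class"),
      identity_properties = vapply(r$properties, function(p)
        look(p, "property"), character(1), USE.NAMES = FALSE),
      behaviour = r$behaviour,
      merged_uri_policy = r$merged_uri_policy,
      fresh_prefix = r$fresh_prefix)
  })
  rules$pattern_bindings <- lapply(rules$pattern_bindings, function(b) {
    b$vars <- lapply(b$vars, function(v) {
      if (v$kind == "individual" && !is.null(v$class))
        v$class_uri <- look(v$class, "class")
      v
    })
    b
  })
  rules$external_links <- lapply(rules$external_links, function(l) {
    if (!is.null(l$class)) l$class_uri <- look(l$class, "class")
    l
  })
  rules
}

## ---- rule application ------------------------------------------------------

registry_key <- function(source_id, entity, local_id, class_uri = NULL) {
  k <- paste(source_id, entity, local_id, sep = "\r")
  if (is.null(class_uri)) k else paste(k, class_uri, sep = "\r")
}

#' Apply an entity rule to one instance
#'
#' Produces the congruent individual for the instance: asserted into the
#' rule's target class, with a URI minted from the rule's token path (or
#' the instance's local id as fallback) and provenance recorded. The
#' individual is NOT yet part of any knowledge base; the engine admits it
#' after the consistency gate and identity resolution.
#'
#' @param rule a resolved entity rule (element of a rule set passed through
#'   validation inside [transform()], or built directly with a `class_uri`).
#' @param instance a [data_instance()].
#' @param kb the target [knowledge_base()] (used for ontology context).
#' @param policy a [uri_policy()].
#' @return an [individual()], or NULL as the skip signal when the rule's
#'   condition is not fulfilled. The result may carry a `warnings`
#'   attribute (e.g. token fallback).
#' @export
apply_entity_rule <- function(rule, instance, kb, policy) {
  warns <- character(0)
  if (!is.null(rule$condition)) {
    ok <- evaluate_condition(rule$condition, instance)
    warns <- c(warns, attr(ok, "warnings"))
    if (!isTRUE(as.logical(ok))) return(NULL)
  }
  token <- instance$local_id
  if (!is.null(rule$uri_token_path)) {
    tv <- resolve_path(instance, rule$uri_token_path)
    if (length(tv)) token <- tv[[1]]
    else warns <- c(warns, paste0("uri token path '", rule$uri_token_path,
                                  "' empty; falling back to local_id"))
  }
  cls <- rule$class_uri %||% rule$target_class
  ind <- individual(
    uri = mint_uri(policy, cls, token),
    classes = cls,
    provenance = data.frame(source_id = instance$source_id,
                            entity = instance$entity,
                            local_id = instance$local_id,
                            stringsAsFactors = FALSE))
  attr(ind, "token") <- token
  if (length(warns)) attr(ind, "warnings") <- warns
  ind
}

#' Apply an attribute rule to an instance/individual pair
#'
#' One data assertion per resolved value; the literal's lexical form equals
#' the source value exactly; the assertion datatype follows the target
#' property's declared range. Values whose lexical form violates the range
#' are withheld (the consistency gate would reject them) and recorded in
#' the `withheld` attribute.
#'
#' @param rule a resolved attribute rule.
#' @param instance the source [data_instance()].
#' @param individual the [individual()] produced for this (entity, class).
#' @param onto the [ontology_model()].
#' @return data.frame(subject, property, value, datatype) of assertions,
#'   with attribute `withheld` (character log entries).
#' @export
apply_attribute_rule <- function(rule, instance, individual, onto) {
  vals <- resolve_path(instance, rule$path)
  prop <- rule$property_uri %||% rule$target_property
  pr <- onto$dprops[[prop]]
  range <- if (!is.null(pr) && !is.na(pr$range)) pr$range else xsd_uri("string")
  withheld <- character(0)
  keep <- logical(length(vals))
  for (i in seq_along(vals)) {
    if (kind_ok(vals[i], xsd_kind(range))) keep[i] <- TRUE
    else withheld <- c(withheld,
                       paste0("value '", vals[i], "' of ", uri_local_name(prop),
                              " violates range ", uri_local_name(range)))
  }
  out <- data.frame(subject = rep(individual$uri, sum(keep)),
                    property = rep(prop, sum(keep)),
                    value = vals[keep],
                    datatype = rep(range, sum(keep)),
                    stringsAsFactors = FALSE)
  attr(out, "withheld") <- withheld
  out
}

#' Apply a relation rule to a link between two transformed instances
#'
#' @param rule a resolved relation rule.
#' @param link list of the two [data_instance()]s, `list(s1=, s2=)`, in the
#'   rule's source order.
#' @param registry named list mapping
#'   `registry_key(source, entity, local_id, class_uri)` to individual URIs.
#' @return data.frame(subject, property, object, external) with one object
#'   assertion, or an object of class `rule_withheld` carrying the reason
#'   when a counterpart individual is missing.
#' @export
apply_relation_rule <- function(rule, link, registry) {
  t1 <- registry[[registry_key(link$s1$source_id, link$s1$entity,
                               link$s1$local_id,
                               rule$t1_uri %||% rule$t1)]]
  t2 <- registry[[registry_key(link$s2$source_id, link$s2$entity,
                               link$s2$local_id,
                               rule$t2_uri %||% rule$t2)]]
  if (is.null(t1) || is.null(t2)) {
    miss <- if (is.null(t1)) link$s1 else link$s2
    return(structure(list(withheld = paste0(
      "relation ", rule$r1, ": no individual for ", miss$entity, "[",
      miss$local_id, "]")), class = "rule_withheld"))
  }
  data.frame(subject = t1, property = rule$r2_uri %||% rule$r2, object = t2,
             external = FALSE, stringsAsFactors = FALSE)
}
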