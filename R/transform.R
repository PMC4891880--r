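## transform_engine: orchestrates the full transformation of one source and
## the integration of many, enforcing the execution order (entity rules ->
## creating pattern statements -> per candidate: remaining pattern content,
## attribute rules, relation rules, identity resolution), the congruence
## relation, and the consistency gate.

#' Construct a run configuration
#'
#' All flags are explicit after construction; nothing defaults implicitly
#' at run time.
#'
#' @param uri_policy a [uri_policy()].
#' @param profile output profile: "rdf" (ground assertions + sameAs) or
#'   "owl" (additionally anonymous-expression memberships and
#'   differentFrom axioms).
#' @param serialization "turtle" or "rdfxml".
#' @param emit_different_from emit pairwise owl:differentFrom within each
#'   identity-ruled class, between individuals with differing complete
#'   keys. Off by default: these axioms are space-consuming and only
#'   needed when downstream reasoning requires explicit distinctness.
#' @param strict_reading strict instance reading (undeclared content is an
#'   error rather than a logged skip).
#' @param reasoner_hook optional character vector: an external command run
#'   on the serialized KB (the file path is appended) whose stdout must
#'   contain "consistent yes" or "consistent no".
#' @param random_seed integer seed fixed for any tie-breaking that samples.
#' @return object of class `run_config`.
#' @export
run_config <- function(uri_policy,
                       profile = c("rdf", "owl"),
                       serialization = c("turtle", "rdfxml"),
                       emit_different_from = FALSE,
                       strict_reading = TRUE,
                       reasoner_hook = NULL,
                       random_seed = 0L) {
  stopifnot(inherits(uri_policy, "uri_policy"))
  structure(list(uri_policy = uri_policy,
                 profile = match.arg(profile),
                 serialization = match.arg(serialization),
                 emit_different_from = isTRUE(emit_different_from),
                 strict_reading = isTRUE(strict_reading),
                 reasoner_hook = reasoner_hook,
                 random_seed = as.integer(random_seed)),
            class = "run_config")
}

## Build the candidate's own individual record from its batch (everything
## with the candidate's subject URI rolled into one individual).
batch_individual <- function(batch, uri) {
  base <- NULL
  for (ind in batch$individuals)
    if (ind$uri == uri) base <- if (is.null(base)) ind
                                else merge_individual_records(base, ind)
  if (is.null(base)) base <- individual(uri, provenance = data.frame(
    source_id = "engine", entity = "", local_id = uri,
    stringsAsFactors = FALSE))
  for (a in batch$class_assert) {
    if (a$subject != uri) next
    if (inherits(a$class, "class_expr")) base$exprs <- c(base$exprs, list(a$class))
    else base$classes <- unique(c(base$classes, a$class))
  }
  d <- batch$data[batch$data$subject == uri, , drop = FALSE]
  if (nrow(d)) base$data <- unique(rbind(base$data, d[c("property", "value", "datatype")]))
  o <- batch$objects[batch$objects$subject == uri, , drop = FALSE]
  if (nrow(o)) base$objects <- unique(rbind(base$objects, o[c("property", "object", "external")]))
  ex <- base$exprs
  base$exprs <- ex[!duplicated(vapply(ex, expr_key, character(1)))]
  base
}

## remainder of a batch once the candidate's own individual is extracted
batch_without_subject <- function(batch, uri) {
  axiom_batch(
    individuals = Filter(function(x) x$uri != uri, batch$individuals),
    class_assert = Filter(function(a) a$subject != uri, batch$class_assert),
    data = batch$data[batch$data$subject != uri, , drop = FALSE],
    objects = batch$objects[batch$objects$subject != uri, , drop = FALSE])
}

#' Transform one source into the knowledge base
#'
#' Runs the mapping in the fixed order: (1) entity rules generate the
#' candidate set I; (2) pattern statements that create new individuals add
#' to I; then per candidate (3a) remaining pattern content, (3b) attribute
#' rules, (3c) relation rules (forward references resolved in a second
#' pass), (3d) the consistency gate followed by identity resolution. An
#' inadmissible candidate batch is discarded whole with a logged
#' violation; an incomplete identity key rejects the candidate. The result
#' is deterministic for fixed inputs and configuration.
#'
#' @param schema the [input_schema()].
#' @param instances list of [data_instance()] from the source.
#' @param rules a validated [mapping_rule_set()].
#' @param patterns named list of [parse_pattern()] results.
#' @param onto the target [ontology_model()].
#' @param config a [run_config()].
#' @param state internal continuation state (used by [integrate()]).
#' @return object of class `transform_result` with fields `kb`,
#'   `individuals` (URIs admitted this run), `log`, `stats`, and internal
#'   continuation fields.
#' @export
transform <- function(schema, instances, rules, patterns = list(), onto,
                      config, state = NULL) {
  vr <- validate_mapping(rules, schema, onto,
                         patterns = if (length(patterns)) patterns else NULL)
  if (nrow(vr))
    stop("refuse-to-run: mapping validation failed (", nrow(vr),
         " finding(s)); first: ", vr$kind[1], " - ", vr$detail[1])
  rules <- resolve_mapping(rules, onto)
  set.seed(config$random_seed)
  policy <- config$uri_policy
  kb <- state$kb %||% knowledge_base(onto)
  key_index <- state$key_index %||% list()
  rewrites <- state$rewrites %||% character(0)
  log <- new_log()
  registry <- list()
  tokens <- character(0)
  candidates <- list()
  cand_index <- list()
  add_candidate <- function(ind, instance) {
    uri <- ind$uri
    if (!is.null(cand_index[[uri]])) {
      i <- cand_index[[uri]]
      candidates[[i]]$batch$individuals <<-
        c(candidates[[i]]$batch$individuals, list(ind))
      ## same URI = same individual: the candidate accumulates every
      ## contributing instance so attribute rules apply to all of them
      candidates[[i]]$instances <<-
        c(candidates[[i]]$instances, list(instance))
    } else {
      candidates[[length(candidates) + 1L]] <<-
        list(uri = uri, instances = list(instance),
             batch = axiom_batch(individuals = list(ind)))
      cand_index[[uri]] <<- length(candidates)
    }
    tokens[uri] <<- attr(ind, "token") %||% uri_local_name(uri)
  }
  graph <- instance_graph(instances)

  ## ---- step 1: basic entity rules -> candidate set I ----------------------
  for (ins in instances) {
    for (r in rules$entity_rules) {
      if (r$source_entity != ins$entity) next
      ind <- apply_entity_rule(r, ins, kb, policy)
      if (is.null(ind)) {
        log <- log_add(log, "entity-rules", "skip", "condition not fulfilled",
                       ins$source_id, ins$entity, ins$local_id)
        next
      }
      for (w in attr(ind, "warnings") %||% character(0))
        log <- log_add(log, "entity-rules", "warning", w,
                       ins$source_id, ins$entity, ins$local_id)
      kf <- registry_key(ins$source_id, ins$entity, ins$local_id, r$class_uri)
      ka <- registry_key(ins$source_id, ins$entity, ins$local_id)
      registry[[kf]] <- ind$uri
      if (is.null(registry[[ka]])) registry[[ka]] <- ind$uri
      add_candidate(ind, ins)
      log <- log_add(log, "entity-rules", "candidate", ind$uri,
                     ins$source_id, ins$entity, ins$local_id)
    }
  }

  ## ---- step 2 + 3a: pattern instantiation ---------------------------------
  ## Creating statements execute first (new individuals join I, logged under
  ## pattern-create); the rest of each pattern's statements are distributed
  ## to the candidates they enrich (pattern-content).
  for (b in rules$pattern_bindings) {
    pat <- patterns[[b$pattern]]
    if (is.null(pat)) stop("refuse-to-run: binding references unknown pattern '",
                           b$pattern, "'")
    attr(b, "prefixes") <- rules$prefixes
    ctx_entity <- {
      ents <- vapply(b$vars, `[[`, character(1), "entity")
      if (length(ents) == 0L)
        stop("refuse-to-run: binding for '", b$pattern, "' binds no variable")
      ents[[1]]
    }
    for (ins in instances) {
      if (ins$entity != ctx_entity) next
      if (!is.null(b$condition)) {
        ok <- evaluate_condition(b$condition, ins)
        for (w in attr(ok, "warnings"))
          log <- log_add(log, "pattern-create", "warning", w,
                         ins$source_id, ins$entity, ins$local_id)
        if (!isTRUE(as.logical(ok))) {
          log <- log_add(log, "pattern-create", "skip",
                         paste0(b$pattern, ": condition not fulfilled"),
                         ins$source_id, ins$entity, ins$local_id)
          next
        }
      }
      pb <- instantiate_pattern(pat, b, list(instance = ins, graph = graph),
                                registry, policy, onto, tokens)
      if (inherits(pb, "pattern_skip")) {
        log <- log_add(log, "pattern-create", "skip",
                       paste0(b$pattern, ": ", attr(pb, "skip")),
                       ins$source_id, ins$entity, ins$local_id)
        next
      }
      tokens <- c(tokens, attr(pb, "tokens")[setdiff(names(attr(pb, "tokens")),
                                                     names(tokens))])
      for (ind in pb$individuals) {
        add_candidate(ind, ins)
        log <- log_add(log, "pattern-create", "candidate",
                       paste0(b$pattern, ": ", ind$uri),
                       ins$source_id, ins$entity, ins$local_id)
      }
      ## distribute remaining statements to their subject candidates
      for (a in pb$class_assert) {
        i <- cand_index[[a$subject]]
        if (is.null(i)) next
        candidates[[i]]$batch$class_assert <-
          c(candidates[[i]]$batch$class_assert, list(a))
      }
      if (nrow(pb$data)) for (j in seq_len(nrow(pb$data))) {
        i <- cand_index[[pb$data$subject[j]]]
        if (is.null(i)) next
        candidates[[i]]$batch$data <-
          unique(rbind(candidates[[i]]$batch$data, pb$data[j, , drop = FALSE]))
      }
      if (nrow(pb$objects)) for (j in seq_len(nrow(pb$objects))) {
        i <- cand_index[[pb$objects$subject[j]]]
        if (is.null(i)) next
        candidates[[i]]$batch$objects <-
          unique(rbind(candidates[[i]]$batch$objects,
                       pb$objects[j, , drop = FALSE]))
      }
      log <- log_add(log, "pattern-content", "instantiated", b$pattern,
                     ins$source_id, ins$entity, ins$local_id)
    }
  }

  ## ---- step 3b: attribute rules -------------------------------------------
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    own <- batch_individual(cand$batch, cand$uri)
    for (ins in cand$instances) {
      for (r in rules$attribute_rules) {
        if (r$source_entity != ins$entity) next
        if (!r$class_uri %in% own$classes) next
        da <- apply_attribute_rule(r, ins, own, onto)
        for (w in attr(da, "withheld") %||% character(0))
          log <- log_add(log, "attribute-rules", "withheld", w,
                         ins$source_id, ins$entity, ins$local_id)
        if (nrow(da))
          candidates[[i]]$batch$data <-
            unique(rbind(candidates[[i]]$batch$data, da))
      }
    }
  }

  ## ---- step 3c: relation rules (second pass so forward references and
  ## document order cannot matter) --------------------------------------------
  for (ins in instances) {
    for (l in ins$links) {
      for (r in rules$relation_rules) {
        if (r$r1 != l$relation) next
        tgt_key <- registry_key(ins$source_id, l$target_entity,
                                l$target_local_id)
        tgt <- graph$nodes[[tgt_key]]
        if (is.null(tgt)) next
        pair <- if (identical(c(ins$entity, tgt$entity), c(r$s1, r$s2)))
          list(s1 = ins, s2 = tgt)
        else if (identical(c(ins$entity, tgt$entity), c(r$s2, r$s1)))
          list(s1 = tgt, s2 = ins)
        else next
        oa <- apply_relation_rule(r, pair, registry)
        if (inherits(oa, "rule_withheld")) {
          log <- log_add(log, "relation-rules", "withheld", oa$withheld,
                         ins$source_id, ins$entity, ins$local_id)
          next
        }
        i <- cand_index[[oa$subject]]
        if (!is.null(i))
          candidates[[i]]$batch$objects <-
            unique(rbind(candidates[[i]]$batch$objects, oa))
      }
    }
  }

  ## ---- step 3d: consistency gate + identity resolution, per candidate -----
  admitted <- character(0)
  rejected <- character(0)
  pending <- list()   # deferred object assertions (forward references)
  find_rule <- function(classes) {
    for (r in rules$identity_rules) {
      for (cl in classes)
        if (r$target_class %in% ancestors_of(onto, cl)) return(r)
    }
    NULL
  }
  for (cand in candidates) {
    uri <- cand$uri
    batch <- cand$batch
    prov <- cand$instances[[1]]
    in_batch <- vapply(batch$individuals, `[[`, character(1), "uri")
    ## defer object assertions whose target is neither in the KB, external,
    ## nor part of this batch
    if (nrow(batch$objects)) {
      ok_tgt <- batch$objects$external |
        batch$objects$object %in% names(kb$individuals) |
        batch$objects$object %in% in_batch
      if (any(!ok_tgt)) {
        pending <- c(pending,
                     split(batch$objects[!ok_tgt, , drop = FALSE],
                           seq_len(sum(!ok_tgt))))
        batch$objects <- batch$objects[ok_tgt, , drop = FALSE]
      }
    }
    viol <- check_consistency(kb, batch, subjects = batch_subject_uris(batch))
    if (nrow(viol)) {
      rejected <- c(rejected, uri)
      for (j in seq_len(nrow(viol)))
        log <- log_add(log, "consistency-gate", "discard",
                       paste0(viol$kind[j], ": ", viol$detail[j]),
                       prov$source_id %||% "", prov$entity %||% "",
                       prov$local_id %||% "")
      next
    }
    own <- batch_individual(batch, uri)
    if (uri %in% names(kb$individuals)) {
      ## same URI = same individual, regardless of identity rules
      kb <- assert_axioms(kb, batch)
      admitted <- unique(c(admitted, uri))
      log <- log_add(log, "identity", "same-uri", uri,
                     prov$source_id %||% "", prov$entity %||% "",
                     prov$local_id %||% "")
      next
    }
    ir <- find_rule(own$classes)
    if (is.null(ir)) {
      kb <- assert_axioms(kb, batch)
      admitted <- c(admitted, uri)
      log <- log_add(log, "identity", "admit", uri,
                     prov$source_id %||% "", prov$entity %||% "",
                     prov$local_id %||% "")
      next
    }
    dec <- tryCatch(
      resolve_identity(own, kb, ir, key_index, rewrites),
      error = function(e) list(decision = "ambiguous",
                               existing = NA_character_, key = NULL,
                               message = conditionMessage(e)))
    if (dec$decision == "ambiguous") {
      rejected <- c(rejected, uri)
      log <- log_add(log, "identity", "reject-ambiguous", dec$message,
                     prov$source_id %||% "", prov$entity %||% "",
                     prov$local_id %||% "")
    } else if (dec$decision == "reject-incomplete") {
      rejected <- c(rejected, uri)
      log <- log_add(log, "identity", "reject-incomplete",
                     paste0("identity key incomplete for ", uri),
                     prov$source_id %||% "", prov$entity %||% "",
                     prov$local_id %||% "")
    } else if (dec$decision == "unique") {
      kb <- assert_axioms(kb, batch)
      admitted <- c(admitted, uri)
      key_index[[key_string(dec$key)]] <- uri
      log <- log_add(log, "identity", "admit-unique", uri,
                     prov$source_id %||% "", prov$entity %||% "",
                     prov$local_id %||% "")
    } else if (dec$decision == "merge") {
      rest <- batch_without_subject(batch, uri)
      kb2 <- tryCatch(assert_axioms(kb, rest), error = function(e) NULL)
      m <- if (is.null(kb2)) list(kb = kb, ok = FALSE, uri = dec$existing,
                                  reason = "companion batch failed")
           else merge_individuals(kb2, dec$existing, own, ir)
      if (m$ok) {
        kb <- m$kb
        rewrites[uri] <- m$uri
        if (m$uri != dec$existing) {
          ## fresh-prefix re-mint: forward the old survivor too
          rewrites[dec$existing] <- m$uri
          key_index[[key_string(dec$key)]] <- m$uri
          admitted[admitted == dec$existing] <- m$uri
        }
        admitted <- unique(c(admitted, m$uri))
        log <- log_add(log, "identity", "merge",
                       paste0(uri, " -> ", m$uri),
                       prov$source_id %||% "", prov$entity %||% "",
                       prov$local_id %||% "")
      } else {
        rejected <- c(rejected, uri)
        log <- log_add(log, "identity", "reject-merge", m$reason,
                       prov$source_id %||% "", prov$entity %||% "",
                       prov$local_id %||% "")
      }
    } else if (dec$decision == "link") {
      kb <- assert_axioms(kb, batch)
      admitted <- c(admitted, uri)
      kb <- link_individuals(kb, dec$existing, uri)
      log <- log_add(log, "identity", "link",
                     paste0(uri, " sameAs ", dec$existing),
                     prov$source_id %||% "", prov$entity %||% "",
                     prov$local_id %||% "")
    }
  }

  ## ---- second pass: deferred object assertions ----------------------------
  for (row in pending) {
    s <- row$subject; o <- row$object
    s2 <- if (!is.na(rewrites[s])) unname(rewrites[s]) else s
    o2 <- if (!is.na(rewrites[o])) unname(rewrites[o]) else o
    if (!s2 %in% names(kb$individuals)) {
      log <- log_add(log, "relation-repair", "dropped",
                     paste0("subject ", s, " not admitted"))
      next
    }
    if (!row$external && !o2 %in% names(kb$individuals)) {
      log <- log_add(log, "relation-repair", "withheld",
                     paste0("target ", o, " not admitted"))
      next
    }
    b <- axiom_batch(objects = data.frame(subject = s2, property = row$property,
                                          object = o2, external = row$external,
                                          stringsAsFactors = FALSE))
    viol <- check_consistency(kb, b, subjects = s2)
    if (nrow(viol)) {
      log <- log_add(log, "relation-repair", "dropped",
                     paste0(viol$kind[1], ": ", viol$detail[1]))
      next
    }
    kb <- assert_axioms(kb, b)
    if (s2 != s || o2 != o)
      log <- log_add(log, "relation-repair", "rewritten",
                     paste0(s, " -> ", s2, " / ", o, " -> ", o2))
  }
  ## repair references to merged-away URIs that entered through batches
  if (length(rewrites)) kb <- rewrite_kb_uris(kb, rewrites)

  ## ---- external sameAs links ----------------------------------------------
  for (l in rules$external_links) {
    for (ins in instances) {
      if (ins$entity != l$entity) next
      key <- if (!is.null(l$class_uri))
        registry_key(ins$source_id, ins$entity, ins$local_id, l$class_uri)
      else registry_key(ins$source_id, ins$entity, ins$local_id)
      uri <- registry[[key]]
      if (is.null(uri)) next
      uri <- if (!is.na(rewrites[uri])) unname(rewrites[uri]) else uri
      if (!uri %in% names(kb$individuals)) next
      tok <- if (!is.null(l$token_path)) resolve_path(ins, l$token_path)
             else ins$local_id
      if (length(tok) == 0L) {
        log <- log_add(log, "external-links", "skip",
                       paste0("token path '", l$token_path, "' empty"),
                       ins$source_id, ins$entity, ins$local_id)
        next
      }
      ext <- paste0(l$base, pct_encode(tok[[1]]))
      kb <- link_individuals(kb, uri, ext)
      log <- log_add(log, "external-links", "link",
                     paste0(uri, " sameAs ", ext),
                     ins$source_id, ins$entity, ins$local_id)
    }
  }

  ## ---- optional owl:differentFrom emission --------------------------------
  if (config$emit_different_from) {
    for (ir in rules$identity_rules) {
      members <- Filter(function(ind) rule_applies(ir, ind, onto),
                        kb$individuals)
      keyed <- list()
      for (ind in members) {
        k <- tryCatch(identity_key(ind, ir, kb, rewrites),
                      error = function(e) "incomplete")
        if (!identical(k, "incomplete")) keyed[[ind$uri]] <- key_string(k)
      }
      uris <- c_sort(names(keyed))
      if (length(uris) > 1L) {
        for (i in seq_len(length(uris) - 1L)) for (j in (i + 1L):length(uris)) {
          if (keyed[[uris[i]]] != keyed[[uris[j]]])
            kb$different_from <- normalize_pairs(
              rbind(kb$different_from, c(uris[i], uris[j])))
        }
      }
    }
  }

  stats <- list(
    instances = as.list(table(vapply(instances, `[[`, character(1), "entity"))),
    individuals = length(kb$individuals),
    admitted = length(admitted),
    rejected = length(unique(rejected)),
    same_as = nrow(kb$same_as),
    actions = as.list(table(vapply(log, `[[`, character(1), "action"))))

  structure(list(kb = kb, individuals = admitted, log = log, stats = stats,
                 registry = registry, rewrites = rewrites,
                 key_index = key_index, tokens = tokens),
            class = "transform_result")
}

#' @export
print.transform_result <- function(x, ...) {
  cat("<transform_result> ", length(x$individuals), " admitted individuals; KB holds ",
      length(x$kb$individuals), " individuals, ", nrow(x$kb$same_as),
      " sameAs pairs; ", length(x$log), " log records\n", sep = "")
  invisible(x)
}

#' Check the congruence of a transformed instance and its individual
#'
#' An individual is congruent with its source instance when (a) every
#' applicable attribute rule's source values appear among its data
#' assertions and every applicable relation rule whose counterpart was
#' admitted is realized by an object assertion, and (b) the individual
#' participates in no structural consistency violation.
#'
#' @param instance the source [data_instance()].
#' @param uri the individual's URI (post-merge URI if it was merged).
#' @param rules the [mapping_rule_set()] used for the run.
#' @param kb the resulting [knowledge_base()].
#' @param registry,rewrites the transform result's registry and rewrite
#'   map, enabling the relation-rule check; relation checks are skipped
#'   when `registry` is NULL.
#' @return list(congruent = logical, failures = character vector).
#' @export
check_congruence <- function(instance, uri, rules, kb, registry = NULL,
                             rewrites = character(0)) {
  onto <- kb$ontology
  rules <- resolve_mapping(rules, onto)
  ind <- kb$individuals[[uri]]
  if (is.null(ind)) stop("unknown individual ", uri)
  fails <- character(0)
  for (r in rules$attribute_rules) {
    if (r$source_entity != instance$entity) next
    if (!r$class_uri %in% ind$classes) next
    vals <- resolve_path(instance, r$path)
    have <- ind$data$value[ind$data$property == r$property_uri]
    miss <- setdiff(vals, have)
    ## values withheld for range violations are logged, not congruent
    for (v in miss)
      fails <- c(fails, paste0("missing data assertion ",
                               uri_local_name(r$property_uri), " = '", v, "'"))
  }
  if (!is.null(registry)) {
    for (l in instance$links) {
      for (r in rules$relation_rules) {
        if (r$r1 != l$relation) next
        tgt_entities <- c(r$s1, r$s2)
        if (!instance$entity %in% tgt_entities) next
        other_entity <- if (instance$entity == r$s1) r$s2 else r$s1
        if (l$target_entity != other_entity) next
        tkey <- registry_key(instance$source_id, l$target_entity,
                             l$target_local_id,
                             if (instance$entity == r$s1) r$t2_uri else r$t1_uri)
        turi <- registry[[tkey]]
        if (is.null(turi)) next
        turi <- if (!is.na(rewrites[turi])) unname(rewrites[turi]) else turi
        if (!turi %in% names(kb$individuals)) next  # counterpart not admitted
        if (instance$entity == r$s1) {
          hit <- any(ind$objects$property == r$r2_uri &
                     ind$objects$object == turi)
          if (!hit)
            fails <- c(fails, paste0("missing object assertion ",
                                     uri_local_name(r$r2_uri), " -> ", turi))
        } else {
          tind <- kb$individuals[[turi]]
          hit <- any(tind$objects$property == r$r2_uri &
                     tind$objects$object == uri)
          if (!hit)
            fails <- c(fails, paste0("missing inverse object assertion ",
                                     uri_local_name(r$r2_uri), " from ", turi))
        }
      }
    }
  }
  rep <- check_consistency(kb)
  mine <- rep[rep$subject == uri, , drop = FALSE]
  for (j in seq_len(nrow(mine)))
    fails <- c(fails, paste0("violation ", mine$kind[j], ": ", mine$detail[j]))
  list(congruent = length(fails) == 0L, failures = fails)
}

#' Integrate several sources into one knowledge base
#'
#' Applies [transform()] to each source in order against the same target
#' ontology and one shared knowledge base, so identity rules act across
#' sources: equivalent entities merge or link according to their rules,
#' and the ontology provides the common vocabulary. A source carrying a
#' different ontology is refused.
#'
#' @param sources ordered list; each element is
#'   `list(schema=, instances=, rules=, ontology=?)` (the optional
#'   per-source ontology must equal `onto`).
#' @param patterns named list of patterns shared by all sources.
#' @param onto the common [ontology_model()].
#' @param config a [run_config()].
#' @return a `transform_result` over the shared KB; its log concatenates
#'   the per-source logs.
#' @export
integrate <- function(sources, patterns = list(), onto, config) {
  digest <- attr(onto, "source_digest")
  state <- NULL
  logs <- list()
  admitted <- character(0)
  res <- NULL
  for (src in sources) {
    if (!is.null(src$ontology)) {
      d2 <- attr(src$ontology, "source_digest")
      if (!identical(d2, digest))
        stop("refuse-to-run: source mapped to a different ontology")
    }
    res <- transform(src$schema, src$instances, src$rules, patterns, onto,
                     config, state = state)
    logs <- c(logs, res$log)
    admitted <- unique(c(admitted, res$individuals))
    state <- list(kb = res$kb, key_index = res$key_index,
                  rewrites = res$rewrites)
  }
  if (is.null(res)) stop("integrate: no sources given")
  ## forward merged-away URIs accumulated across sources
  admitted <- unique(vapply(admitted, function(u) {
    while (!is.na(res$rewrites[u])) u <- unname(res$rewrites[u])
    u
  }, character(1), USE.NAMES = FALSE))
  admitted <- admitted[admitted %in% names(res$kb$individuals)]
  res$log <- logs
  res$individuals <- admitted
  res$stats$admitted <- length(admitted)
  res
}

#' Keyed canonical form of a knowledge base
#'
#' A canonical rendering in which each individual's URI is replaced by a
#' content-derived token: its identity key when a rule yields a complete
#' key, otherwise its classes, data assertions and provenance local ids.
#' Two runs over permuted inputs in merge mode agree on this form even
#' when first-wins URI choices differ.
#'
#' @param kb a [knowledge_base()].
#' @param identity_rules list of resolved [identity_rule()] objects.
#' @return character scalar.
#' @export
keyed_canonical <- function(kb, identity_rules = list()) {
  map <- character(0)
  for (u in c_sort(names(kb$individuals))) {
    ind <- kb$individuals[[u]]
    tok <- NULL
    for (ir in identity_rules) {
      if (!rule_applies(ir, ind, kb$ontology)) next
      k <- tryCatch(identity_key(ind, ir, kb), error = function(e) "incomplete")
      if (!identical(k, "incomplete")) {
        tok <- paste0("key:", key_string(k)); break
      }
    }
    if (is.null(tok))
      tok <- paste0("anon:", paste(c_sort(ind$classes), collapse = ","), "|",
                    paste(c_sort(paste0(ind$data$property, "=", ind$data$value)),
                          collapse = ";"), "|",
                    paste(c_sort(paste0(ind$provenance$entity, ":",
                                        ind$provenance$local_id)),
                          collapse = ";"))
    map[u] <- tok
  }
  ## identity-keyed tokens may collide only for genuinely identical content;
  ## make tokens injective per distinct URI set by disambiguating duplicates
  lines <- character(0)
  sub1 <- function(x) { r <- map[x]; ifelse(is.na(r), x, unname(r)) }
  for (u in names(kb$individuals)) {
    ind <- kb$individuals[[u]]
    me <- map[[u]]
    lines <- c(lines,
               paste0(me, " class ", c_sort(ind$classes)),
               if (nrow(ind$data))
                 paste0(me, " data ", ind$data$property, " ", ind$data$value,
                        " ", ind$data$datatype),
               if (nrow(ind$objects))
                 paste0(me, " obj ", ind$objects$property, " ",
                        sub1(ind$objects$object)),
               vapply(ind$exprs, function(e) paste0(me, " expr ", expr_key(e)),
                      character(1)))
  }
  if (nrow(kb$same_as)) {
    sp <- cbind(sub1(kb$same_as[, 1]), sub1(kb$same_as[, 2]))
    sp <- t(apply(sp, 1L, c_sort))
    lines <- c(lines, paste0("sameas ", sp[, 1], " ", sp[, 2]))
  }
  paste(c_sort(lines), collapse = "\n")
}

#' Run the external reasoner hook on a knowledge base
#'
#' Serializes the KB (owl profile) to a temporary file, appends its path to
#' the configured command, and parses "consistent yes" / "consistent no"
#' from the output.
#'
#' @param kb a [knowledge_base()].
#' @param config a [run_config()] with a non-NULL `reasoner_hook`.
#' @return logical: TRUE if the reasoner reports consistency.
#' @export
invoke_reasoner <- function(kb, config) {
  if (is.null(config$reasoner_hook)) stop("no reasoner hook configured")
  path <- tempfile(fileext = ".ttl")
  writeLines(serialize_kb(kb, "turtle", "owl", override = TRUE), path)
  on.exit(unlink(path))
  cmd <- config$reasoner_hook
  out <- suppressWarnings(
    system2(cmd[1], args = shQuote(c(cmd[-1], path)),
            stdout = TRUE, stderr = TRUE))
  txt <- paste(out, collapse = "\n")
  if (grepl("consistent\\s+yes", txt)) TRUE
  else if (grepl("consistent\\s+no", txt)) FALSE
  else stop("reasoner hook produced no verdict: ", txt)
}
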