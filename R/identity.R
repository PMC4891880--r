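## identity_engine: deciding when two individuals denote the same domain
## entity. An identity rule names the property set IR that univocally
## identifies individuals of a class; equal complete key tuples mean the
## same entity, resolved by merging or owl:sameAs linkage.

#' Construct an identity rule
#'
#' @param target_class class URI the rule governs (subclasses inherit it).
#' @param identity_properties non-empty character vector of property URIs
#'   (datatype and/or object properties) forming the identity set IR.
#' @param behaviour "merge" (duplicates collapse into one individual) or
#'   "link" (duplicates co-exist, connected by owl:sameAs).
#' @param merged_uri_policy "first-wins" (the earlier individual's URI
#'   survives a merge) or "fresh-prefix" (a new URI is minted from
#'   `fresh_prefix` plus a digest of the key).
#' @param fresh_prefix URI base required by the fresh-prefix policy.
#' @return object of class `identity_rule`.
#' @export
identity_rule <- function(target_class, identity_properties,
                          behaviour = c("merge", "link"),
                          merged_uri_policy = c("first-wins", "fresh-prefix"),
                          fresh_prefix = NULL) {
  behaviour <- match.arg(behaviour)
  merged_uri_policy <- match.arg(merged_uri_policy)
  if (length(identity_properties) == 0L)
    stop("identity rule needs at least one property")
  if (merged_uri_policy == "fresh-prefix" && is.null(fresh_prefix))
    stop("fresh-prefix policy needs a fresh_prefix base")
  structure(list(target_class = target_class,
                 identity_properties = identity_properties,
                 behaviour = behaviour,
                 merged_uri_policy = merged_uri_policy,
                 fresh_prefix = fresh_prefix),
            class = "identity_rule")
}

rule_applies <- function(rule, ind, onto) {
  any(vapply(ind$classes, function(cl)
    rule$target_class %in% ancestors_of(onto, cl), logical(1)))
}

#' Compute the identity key of an individual under a rule
#'
#' The key is the ordered tuple of the rule's property values: the literal
#' lexical form for datatype properties, the object URI canonicalized
#' through the sameAs closure representative for object properties. A
#' missing property yields the incomplete signal (never a partial key); a
#' multi-valued identity property is an ambiguity error.
#'
#' @param ind an [individual()] (asserted into the rule's class or a
#'   subclass).
#' @param rule an [identity_rule()].
#' @param kb the [knowledge_base()] providing the sameAs closure and the
#'   ontology.
#' @param rewrites named character vector of URI rewrites (merged-away URI
#'   -> survivor) applied before canonicalization.
#' @return object of class `identity_key` (fields `class`, `tuple`), or
#'   the character scalar "incomplete" when any property lacks a value.
#' @export
identity_key <- function(ind, rule, kb, rewrites = character(0)) {
  reps <- sameas_representatives(kb)
  onto <- kb$ontology
  tuple <- character(length(rule$identity_properties))
  for (i in seq_along(rule$identity_properties)) {
    p <- rule$identity_properties[i]
    if (!is.null(onto$dprops[[p]])) {
      vals <- unique(ind$data$value[ind$data$property == p])
    } else {
      vals <- unique(ind$objects$object[ind$objects$property == p])
      if (length(vals)) {
        r <- rewrites[vals]
        vals <- ifelse(is.na(r), vals, unname(r))
        vals <- unique(canon_uri(vals, reps))
      }
    }
    if (length(vals) == 0L) return("incomplete")
    if (length(vals) > 1L)
      stop("ambiguity error: identity property ", uri_local_name(p),
           " is multi-valued on ", ind$uri)
    tuple[i] <- vals
  }
  structure(list(class = rule$target_class, tuple = tuple),
            class = "identity_key")
}

key_string <- function(key) {
  paste(c(key$class, key$tuple), collapse = "\r")
}

#' Resolve the identity of a candidate individual
#'
#' @param candidate an [individual()] not yet in the KB.
#' @param kb the [knowledge_base()].
#' @param rule the applicable [identity_rule()].
#' @param key_index named list mapping key strings to the URI of the
#'   first-admitted individual holding that key (maintained by the engine;
#'   recomputed from the KB when NULL).
#' @param rewrites URI rewrite map as in [identity_key()].
#' @return list(decision = "unique" | "merge" | "link" |
#'   "reject-incomplete", existing = URI or NA, key = the key or NULL).
#' @export
resolve_identity <- function(candidate, kb, rule, key_index = NULL,
                             rewrites = character(0)) {
  key <- identity_key(candidate, rule, kb, rewrites)
  if (identical(key, "incomplete"))
    return(list(decision = "reject-incomplete", existing = NA_character_,
                key = NULL))
  ks <- key_string(key)
  if (is.null(key_index)) key_index <- kb_key_index(kb, rule, rewrites)
  existing <- key_index[[ks]]
  if (is.null(existing) || identical(existing, candidate$uri))
    return(list(decision = "unique", existing = NA_character_, key = key))
  list(decision = rule$behaviour, existing = existing, key = key)
}

## brute-force key index over the current KB (used when the engine's
## incremental index is not supplied)
kb_key_index <- function(kb, rule, rewrites = character(0)) {
  idx <- list()
  for (u in c_sort(names(kb$individuals))) {
    ind <- kb$individuals[[u]]
    if (!rule_applies(rule, ind, kb$ontology)) next
    key <- tryCatch(identity_key(ind, rule, kb, rewrites),
                    error = function(e) "incomplete")
    if (identical(key, "incomplete")) next
    ks <- key_string(key)
    if (is.null(idx[[ks]])) idx[[ks]] <- u
  }
  idx
}

#' Merge a duplicate individual into a surviving one
#'
#' The union of asserted classes, data assertions, object assertions and
#' provenance lands on the survivor; the duplicate never enters the KB as
#' a separate individual. Under "first-wins" the earlier URI survives;
#' under "fresh-prefix" the merged individual is re-minted at the
#' configured prefix plus a digest of the identity key. If the union would
#' put conflicting values on an identity property, or would make the KB
#' inconsistent, the merge is aborted.
#'
#' @param kb the [knowledge_base()].
#' @param survivor_uri URI of the individual already in the KB.
#' @param duplicate the incoming [individual()] with an equal identity key.
#' @param rule the governing [identity_rule()].
#' @return list(kb = updated KB, uri = surviving URI, ok = logical,
#'   reason = character). On abort (`ok = FALSE`) the KB is unchanged.
#' @export
merge_individuals <- function(kb, survivor_uri, duplicate, rule) {
  surv <- kb$individuals[[survivor_uri]]
  if (is.null(surv)) stop("merge: survivor ", survivor_uri, " not in KB")
  dup2 <- duplicate; dup2$uri <- survivor_uri
  merged <- merge_individual_records(surv, dup2)
  ## conflicting values on an identity property abort the merge
  for (p in rule$identity_properties) {
    vals <- if (!is.null(kb$ontology$dprops[[p]]))
      unique(merged$data$value[merged$data$property == p])
    else unique(merged$objects$object[merged$objects$property == p])
    if (length(vals) > 1L)
      return(list(kb = kb, uri = survivor_uri, ok = FALSE,
                  reason = paste0("conflicting values on identity property ",
                                  uri_local_name(p))))
  }
  kb2 <- kb
  if (rule$merged_uri_policy == "fresh-prefix") {
    new_uri <- paste0(rule$fresh_prefix,
                      uri_local_name(rule$target_class), "/",
                      pct_encode(paste(
                        vapply(rule$identity_properties, uri_local_name,
                               character(1)), collapse = "_")),
                      "-", substr(key_digest(merged, rule, kb), 1L, 12L))
    merged <- rename_individual(merged, new_uri)
    kb2$individuals[[survivor_uri]] <- NULL
    kb2$individuals[[new_uri]] <- merged
    kb2 <- rewrite_kb_uris(kb2, stats::setNames(new_uri, survivor_uri))
    survivor_uri <- new_uri
  } else {
    kb2$individuals[[survivor_uri]] <- merged
  }
  rep <- check_consistency(kb2, subjects = survivor_uri)
  if (nrow(rep))
    return(list(kb = kb, uri = survivor_uri, ok = FALSE,
                reason = paste0("merge would violate: ", rep$kind[1])))
  list(kb = kb2, uri = survivor_uri, ok = TRUE, reason = "")
}

key_digest <- function(ind, rule, kb) {
  ## small deterministic polynomial digest of the key string
  s <- key_string(identity_key(ind, rule, kb))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 1000000007
  sprintf("%09d", h)
}

rename_individual <- function(ind, new_uri) {
  ind$uri <- new_uri
  ind
}

## rewrite every object assertion, sameAs and differentFrom reference
rewrite_kb_uris <- function(kb, map) {
  sub1 <- function(x) { r <- map[x]; ifelse(is.na(r), x, unname(r)) }
  for (u in names(kb$individuals)) {
    obj <- kb$individuals[[u]]$objects
    if (nrow(obj)) {
      obj$object <- sub1(obj$object)
      kb$individuals[[u]]$objects <- unique(obj)
    }
  }
  if (nrow(kb$same_as)) kb$same_as <- normalize_pairs(apply(kb$same_as, 2L, sub1))
  if (nrow(kb$different_from))
    kb$different_from <- normalize_pairs(apply(kb$different_from, 2L, sub1))
  kb
}

#' Link two individuals with owl:sameAs
#'
#' Both individuals are retained; the unordered pair joins the sameAs set
#' and the closure updates. Linking an individual to itself is a no-op;
#' linking a pair present in differentFrom is refused.
#'
#' @param kb the [knowledge_base()].
#' @param a,b URIs (KB individuals or declared external URIs).
#' @return the updated [knowledge_base()].
#' @export
link_individuals <- function(kb, a, b) {
  if (a == b) return(kb)
  pair <- c_sort(c(a, b))
  if (nrow(kb$different_from)) {
    kd <- paste(kb$different_from[, 1], kb$different_from[, 2])
    if (paste(pair[1], pair[2]) %in% kd)
      stop("sameas-vs-differentfrom violation: pair already differentFrom")
  }
  kb$same_as <- normalize_pairs(rbind(kb$same_as, pair))
  kb
}
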