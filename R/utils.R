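#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Percent-encode a URI token
#'
#' Encodes everything except RFC 3986 unreserved characters so that minted
#' URIs stay absolute, dereferenceable HTTP URIs regardless of the source
#' values used as tokens.
#' @param x character vector of tokens.
#' @return encoded character vector.
#' @keywords internal
pct_encode <- function(x) {
  vapply(x, function(s) utils::URLencode(s, reserved = TRUE), character(1),
         USE.NAMES = FALSE)
}

#' Local name of a URI (text after the last '#' or '/')
#' @keywords internal
uri_local_name <- function(uri) {
  sub(".*[#/]", "", uri)
}

is_absolute_http <- function(uri) {
  grepl("^https?://", uri)
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators never perturb
#' user code.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Run-log: a list of records, each a named list with fixed fields.
new_log <- function() list()

log_add <- function(log, phase, action, detail = "", source_id = "", entity = "",
                    local_id = "") {
  log[[length(log) + 1L]] <- list(
    phase = phase, source_id = source_id, entity = entity,
    local_id = local_id, action = action, detail = detail)
  log
}

#' Convert a run log to a data frame
#' @param log a log list as held in a `transform_result`.
#' @return data.frame with columns phase, source_id, entity, local_id, action, detail.
#' @export
log_frame <- function(log) {
  if (length(log) == 0L)
    return(data.frame(phase = character(), source_id = character(),
                      entity = character(), local_id = character(),
                      action = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(log, function(r)
    data.frame(phase = r$phase, source_id = r$source_id, entity = r$entity,
               local_id = r$local_id, action = r$action, detail = r$detail,
               stringsAsFactors = FALSE)))
}

#' Write a run log as JSON lines
#' @param log log list.
#' @param path output file path.
#' @export
write_log_jsonl <- function(log, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (r in log)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE), con)
  invisible(path)
}

## Literal lexical checks per XSD-style value kinds.
kind_ok <- function(value, kind) {
  switch(kind,
    text = ,
    string = TRUE,
    integer = grepl("^[+-]?[0-9]+$", value),
    decimal = grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$", value),
    boolean = value %in% c("true", "false", "0", "1"),
    TRUE)
}

## Map an xsd datatype URI/local name to a value kind.
xsd_kind <- function(datatype) {
  ln <- uri_local_name(datatype)
  switch(ln,
    integer = , int = , long = , nonNegativeInteger = "integer",
    decimal = , double = , float = "decimal",
    boolean = "boolean",
    "text")
}

## Deterministic sort helper: C-locale ordering of character vectors, so
## canonical serialization is stable across platforms.
c_sort <- function(x) {
  if (length(x) == 0L) return(character(0))
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x, method = "radix")
}

c_order <- function(...) order(..., method = "radix")

## Union-find over URI pairs, used for the owl:sameAs closure.
uf_components <- function(pairs) {
  ## pairs: 2-column character matrix; returns named vector uri -> representative
  if (is.null(pairs) || nrow(pairs) == 0L) return(character(0))
  uris <- c_sort(unique(c(pairs[, 1L], pairs[, 2L])))
  parent <- stats::setNames(uris, uris)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
    if (ra != rb) {
      ## representative = lexicographically smallest, so closure is order-free
      if (ra < rb) parent[[rb]] <- ra else parent[[ra]] <- rb
    }
  }
  vapply(uris, find, character(1))
}
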