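## cli_app: project manifests (one YAML document describing a reproducible
## run) and the command entry points wrapped by exec/ontoetl. All logic
## lives here; the shell script is a thin dispatcher.

#' Read a project manifest
#'
#' A manifest is a YAML document naming the schema, data, ontology,
#' mapping and pattern files of a project plus the run configuration.
#' Relative paths resolve against the manifest's directory. Defaults are
#' applied so the returned RunConfig block is complete.
#'
#' @param path manifest file path.
#' @return list with resolved paths and a complete config block. Missing
#'   referenced files raise an error of class `manifest_missing_file`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(structure(class = c("manifest_missing_file", "error", "condition"),
                   list(message = paste0("manifest not found: ", path),
                        call = NULL)))
  m <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    fp <- if (grepl("^/", p)) p else file.path(base_dir, p)
    if (!file.exists(fp))
      stop(structure(class = c("manifest_missing_file", "error", "condition"),
                     list(message = paste0("referenced file not found: ", fp),
                          call = NULL)))
    fp
  }
  resolve_source <- function(s) {
    s$schema <- resolve(s$schema)
    s$schema_kind <- s$schema_kind %||% "xml"
    s$data <- if (is.list(s$data)) lapply(s$data, resolve) else resolve(s$data)
    s$mapping <- resolve(s$mapping)
    if (!is.null(s$ontology)) s$ontology <- resolve(s$ontology)
    s$source_id <- s$source_id %||% "source"
    s
  }
  if (!is.null(m$sources)) {
    m$sources <- lapply(m$sources, resolve_source)
  } else {
    m <- utils::modifyList(m, resolve_source(m))
  }
  m$ontology <- resolve(m$ontology)
  m$ontology_format <- m$ontology_format %||% "turtle"
  if (length(m$patterns)) m$patterns <- lapply(m$patterns, resolve)
  m$format <- m$format %||% "turtle"
  m$profile <- m$profile %||% "rdf"
  m$emit_different_from <- isTRUE(m$emit_different_from)
  m$strict <- if (is.null(m$strict)) TRUE else isTRUE(m$strict)
  m$seed <- m$seed %||% 0L
  m$base_uri <- m$base_uri %||% "http://example.org/ds/"
  m$output <- m$output %||% "out.ttl"
  if (!grepl("^/", m$output)) m$output <- file.path(base_dir, m$output)
  m
}

manifest_policy <- function(m, onto, prefixes = character(0)) {
  pcb <- character(0); md <- character(0)
  for (cn in names(m$per_class_base %||% list())) {
    cu <- onto_lookup(onto, cn, "class", prefixes)
    if (!is.na(cu)) pcb[cu] <- m$per_class_base[[cn]]
  }
  for (cn in m$adopt_external %||% character(0)) {
    cu <- onto_lookup(onto, cn, "class", prefixes)
    if (!is.na(cu)) md[cu] <- "adopt-external"
  }
  uri_policy(m$base_uri, per_class_base = pcb, mode = md)
}

load_manifest_source <- function(s, m) {
  schema <- if (s$schema_kind == "xml")
    load_xml_schema(paste(readLines(s$schema, warn = FALSE), collapse = "\n"))
  else suppressWarnings(load_tabular_schema(
    paste(readLines(s$schema, warn = FALSE), collapse = "\n")))
  instances <- if (s$schema_kind == "xml")
    read_xml_instances(paste(readLines(s$data, warn = FALSE), collapse = "\n"),
                       schema, s$source_id, strict = m$strict)
  else {
    rows <- lapply(s$data, function(p)
      utils::read.csv(p, stringsAsFactors = FALSE, colClasses = "character"))
    read_tabular_instances(rows, schema, s$source_id, strict = m$strict)
  }
  rules <- parse_mapping_document(
    paste(readLines(s$mapping, warn = FALSE), collapse = "\n"))
  out <- list(schema = schema, instances = instances, rules = rules)
  ## a source may pin its own ontology; integrate() refuses a mismatch
  if (!is.null(s$ontology) && !identical(s$ontology, m$ontology))
    out$ontology <- load_ontology(
      paste(readLines(s$ontology, warn = FALSE), collapse = "\n"),
      m$ontology_format)
  out
}

load_manifest_project <- function(m) {
  onto <- load_ontology(paste(readLines(m$ontology, warn = FALSE),
                              collapse = "\n"),
                        m$ontology_format)
  patterns <- list()
  for (pn in names(m$patterns %||% list()))
    patterns[[pn]] <- parse_pattern(
      paste(readLines(m$patterns[[pn]], warn = FALSE), collapse = "\n"), pn)
  sources <- if (!is.null(m$sources)) lapply(m$sources, load_manifest_source, m = m)
             else list(load_manifest_source(m, m))
  prefixes <- if (length(sources)) sources[[1]]$rules$prefixes else character(0)
  config <- run_config(uri_policy = manifest_policy(m, onto, prefixes),
                       profile = m$profile, serialization = m$format,
                       emit_different_from = m$emit_different_from,
                       strict_reading = m$strict, random_seed = m$seed)
  list(onto = onto, patterns = patterns, sources = sources, config = config)
}

#' Validate a project manifest
#'
#' Parses every referenced file and runs [validate_mapping()] for each
#' source. Status 0 means all validations are empty; status 1 reports
#' findings; status 2 means a referenced file is missing or unreadable.
#'
#' @param manifest_path manifest file path.
#' @return list(status, report) where report is a data frame of findings.
#' @export
cmd_validate <- function(manifest_path) {
  res <- tryCatch({
    m <- read_manifest(manifest_path)
    p <- load_manifest_project(m)
    reports <- lapply(seq_along(p$sources), function(i) {
      s <- p$sources[[i]]
      r <- validate_mapping(s$rules, s$schema, p$onto,
                            patterns = if (length(p$patterns)) p$patterns else NULL)
      if (nrow(r)) r$source <- i
      r
    })
    rep <- do.call(rbind, Filter(nrow, reports))
    if (is.null(rep))
      rep <- data.frame(kind = character(), detail = character(),
                        stringsAsFactors = FALSE)
    list(status = if (nrow(rep)) 1L else 0L, report = rep)
  },
  manifest_missing_file = function(e)
    list(status = 2L, report = data.frame(kind = "missing-file",
                                          detail = conditionMessage(e),
                                          stringsAsFactors = FALSE)),
  error = function(e)
    list(status = 2L, report = data.frame(kind = "load-error",
                                          detail = conditionMessage(e),
                                          stringsAsFactors = FALSE)))
  res
}

run_project <- function(manifest_path, integrate_mode) {
  m <- read_manifest(manifest_path)
  p <- load_manifest_project(m)
  res <- if (integrate_mode || length(p$sources) > 1L)
    integrate(p$sources, p$patterns, p$onto, p$config)
  else
    transform(p$sources[[1]]$schema, p$sources[[1]]$instances,
              p$sources[[1]]$rules, p$patterns, p$onto, p$config)
  list(m = m, p = p, res = res)
}

#' Transform the project described by a manifest
#'
#' Writes the output dataset and a JSON-lines decision log next to it.
#' Status 0 on success; 1 if any candidate batch was discarded by the
#' consistency gate (the dataset is still written) and `fail_on_discard`
#' is FALSE it stays 1, otherwise the dataset is still written but status
#' 1 signals the discards; 2 on load/validation failure.
#'
#' @param manifest_path manifest file path.
#' @param out optional output path override.
#' @param fail_on_discard treat any discarded batch as a failure.
#' @return list(status, output, log_path, result).
#' @export
cmd_transform <- function(manifest_path, out = NULL, fail_on_discard = FALSE) {
  v <- cmd_validate(manifest_path)
  if (v$status != 0L) return(list(status = v$status, report = v$report))
  run <- run_project(manifest_path, integrate_mode = FALSE)
  out_path <- out %||% run$m$output
  doc <- serialize_kb(run$res$kb, run$m$format, run$m$profile)
  writeLines(doc, out_path, sep = "")
  log_path <- paste0(out_path, ".log.jsonl")
  write_log_jsonl(run$res$log, log_path)
  discards <- sum(vapply(run$res$log, function(r)
    r$action == "discard", logical(1)))
  list(status = if (discards > 0L) 1L else 0L, output = out_path,
       log_path = log_path, result = run$res, discards = discards)
}

#' Integrate the multi-source project described by a manifest
#'
#' As [cmd_transform()] over [integrate()]; the manifest must carry a
#' `sources:` list and the shared ontology. Sources declaring different
#' ontologies are refused with status 2.
#'
#' @inheritParams cmd_transform
#' @return list(status, output, log_path, result).
#' @export
cmd_integrate <- function(manifest_path, out = NULL, fail_on_discard = FALSE) {
  v <- cmd_validate(manifest_path)
  if (v$status != 0L) return(list(status = v$status, report = v$report))
  run <- tryCatch(run_project(manifest_path, integrate_mode = TRUE),
                  error = function(e)
                    structure(list(message = conditionMessage(e)),
                              class = "run_refused"))
  if (inherits(run, "run_refused"))
    return(list(status = 2L, report = data.frame(
      kind = "refused", detail = run$message, stringsAsFactors = FALSE)))
  out_path <- out %||% run$m$output
  doc <- serialize_kb(run$res$kb, run$m$format, run$m$profile)
  writeLines(doc, out_path, sep = "")
  log_path <- paste0(out_path, ".log.jsonl")
  write_log_jsonl(run$res$log, log_path)
  discards <- sum(vapply(run$res$log, function(r)
    r$action == "discard", logical(1)))
  list(status = if (discards > 0L) 1L else 0L, output = out_path,
       log_path = log_path, result = run$res, discards = discards)
}

#' Write a named fixture bundle to a directory
#'
#' @param name one of "gene", "molecule", "protein-with-cds",
#'   "protein-without-cds", "uniprot-redefine", "uniprot-link",
#'   "synthetic-pair".
#' @param dir output directory.
#' @param seed seed for the synthetic pair.
#' @return manifest path(s), invisibly.
#' @export
cmd_fixtures <- function(name, dir, seed = 0L) {
  switch(name,
    gene = write_bundle(gene_example(), dir),
    molecule = write_bundle(molecule_example(), dir),
    "protein-with-cds" = write_bundle(protein_pattern_examples()$with_cds, dir),
    "protein-without-cds" =
      write_bundle(protein_pattern_examples()$without_cds, dir),
    "uniprot-redefine" = write_bundle(protein_link_example("redefine"), dir),
    "uniprot-link" = write_bundle(protein_link_example("link"), dir),
    "synthetic-pair" = {
      pair <- synthetic_pair(synthetic_spec(seed = seed))
      p1 <- write_bundle(pair$source1, file.path(dir, "source1"))
      p2 <- write_bundle(pair$source2, file.path(dir, "source2"))
      invisible(c(p1, p2))
    },
    stop("unknown fixture '", name, "'"))
}
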