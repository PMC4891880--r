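## transform_engine: execution order, the consistency gate, congruence,
## integration, determinism

test_that("the orthology example produces the expected individual set and links", {
  b <- gene_example()
  res <- run_bundle(b)
  expect_length(res$kb$individuals, 4L)
  gene <- res$kb$individuals[["http://example.org/orthods/Gene/pyc-1"]]
  expect_false(is.null(gene))
  expect_equal(nrow(gene$data), 1L)
  expect_equal(gene$data$value, "pyc-1")
  expect_equal(nrow(gene$objects), 3L)
  objs <- setNames(gene$objects$object,
                   vapply(gene$objects$property, ontoetl:::uri_local_name,
                          character(1)))
  expect_equal(unname(objs["encodes"]),
               "http://example.org/orthods/Protein/O17732")
  expect_equal(unname(objs["in_taxon"]),
               "http://example.org/orthods/organisms/6239")
  expect_equal(unname(objs["contained_in"]),
               "http://example.org/orthods/database/UniProt")
  expect_equal(nrow(check_consistency(res$kb)), 0L)
})

test_that("the instrumented phase order matches the prescribed execution steps", {
  ## molecule example: entity rules, then creating pattern statements
  ## (Chirality fillers), then pattern content, then identity resolution
  res <- run_bundle(molecule_example(c(1L, 0L, 1L)))
  phases <- vapply(res$log, `[[`, character(1), "phase")
  for (p in c("entity-rules", "pattern-create", "pattern-content", "identity"))
    expect_true(p %in% phases, info = p)
  idx <- function(p) min(which(phases == p))
  expect_lt(idx("entity-rules"), idx("pattern-create"))
  expect_lt(idx("pattern-create"), idx("pattern-content"))
  expect_lt(idx("pattern-content"), idx("identity"))
})

test_that("every admitted instance in the worked example is congruent", {
  b <- gene_example()
  res <- run_bundle(b)
  rules <- ontoetl:::resolve_mapping(b$rules, b$onto)
  for (ins in b$instances) {
    for (er in rules$entity_rules) {
      if (er$source_entity != ins$entity) next
      uri <- res$registry[[ontoetl:::registry_key(
        ins$source_id, ins$entity, ins$local_id, er$class_uri)]]
      cc <- check_congruence(ins, uri, b$rules, res$kb, res$registry,
                             res$rewrites)
      expect_true(cc$congruent, info = paste(ins$entity, uri))
    }
  }
})

test_that("an injected fault breaks congruence through clause (a)", {
  b <- gene_example()
  res <- run_bundle(b)
  gene_uri <- "http://example.org/orthods/Gene/pyc-1"
  res$kb$individuals[[gene_uri]]$data <-
    res$kb$individuals[[gene_uri]]$data[0, , drop = FALSE]
  gene_ins <- Filter(function(i) i$entity == "gene", b$instances)[[1]]
  cc <- check_congruence(gene_ins, gene_uri, b$rules, res$kb, res$registry)
  expect_false(cc$congruent)
  expect_match(cc$failures, "missing data assertion", all = FALSE)
})

test_that("chiral and non-chiral molecules partition exactly as the brute-force filter says", {
  set.seed(31)
  flags <- as.integer(stats::runif(12) < 0.5)
  b <- molecule_example(flags)
  res <- run_bundle(b)
  mols <- Filter(function(ind)
    "http://example.org/mol#Molecule" %in% ind$classes, res$kb$individuals)
  expect_length(mols, length(flags))
  enriched <- vapply(mols, function(ind) length(ind$exprs) > 0L, logical(1))
  expect_equal(sum(enriched), sum(flags == 1L))
  expect_equal(sum(!enriched), sum(flags == 0L))
  ## fillers: one Chirality individual per chiral molecule
  chir <- Filter(function(ind)
    "http://example.org/mol#Chirality" %in% ind$classes, res$kb$individuals)
  expect_length(chir, sum(flags == 1L))
})

test_that("an empty instance stream yields an empty KB and an empty log", {
  b <- gene_example()
  cfg <- bundle_config(b)
  res <- transform(b$schema, list(), b$rules, b$patterns, b$onto, cfg)
  expect_length(res$kb$individuals, 0L)
  expect_length(res$log, 0L)
})

test_that("repeated runs are byte-identical including logs", {
  b <- gene_example()
  r1 <- run_bundle(b); r2 <- run_bundle(b)
  expect_identical(serialize_kb(r1$kb, "turtle", "owl"),
                   serialize_kb(r2$kb, "turtle", "owl"))
  expect_identical(r1$log, r2$log)
})

test_that("swapping source order in merge mode preserves counts and keyed canonical form", {
  spec <- synthetic_spec(seed = 17, n_entities = 25, duplicate_rate = 0.2,
                         overlap = 8)
  p <- synthetic_pair(spec, "merge")
  cfg <- bundle_config(p$source1)
  srcs <- list(
    list(schema = p$source1$schema, instances = p$source1$instances,
         rules = p$source1$rules),
    list(schema = p$source2$schema, instances = p$source2$instances,
         rules = p$source2$rules))
  r12 <- integrate(srcs, list(), p$source1$onto, cfg)
  r21 <- integrate(rev(srcs), list(), p$source1$onto, cfg)
  expect_equal(length(r12$kb$individuals), length(r21$kb$individuals))
  rules <- ontoetl:::resolve_mapping(p$source1$rules, p$source1$onto)
  expect_identical(keyed_canonical(r12$kb, rules$identity_rules),
                   keyed_canonical(r21$kb, rules$identity_rules))
})

test_that("integration refuses a source declaring a different ontology", {
  b <- gene_example()
  other <- tiny_onto()
  cfg <- bundle_config(b)
  expect_error(integrate(list(list(schema = b$schema, instances = b$instances,
                                   rules = b$rules, ontology = other)),
                         b$patterns, b$onto, cfg),
               "different ontology")
})

test_that("differentFrom emission is off by default and keyed when enabled", {
  spec <- synthetic_spec(seed = 5, n_entities = 6, duplicate_rate = 0,
                         overlap = 0)
  p <- synthetic_pair(spec, "merge")
  r_off <- run_bundle(p$source1)
  expect_equal(nrow(r_off$kb$different_from), 0L)
  r_on <- run_bundle(p$source1, emit_different_from = TRUE)
  n <- length(r_on$kb$individuals)
  expect_equal(nrow(r_on$kb$different_from), n * (n - 1L) / 2L)
  expect_equal(nrow(check_consistency(r_on$kb)), 0L)
})

test_that("the run refuses to start on a mapping that does not validate", {
  b <- gene_example()
  bad <- b$rules
  bad$attribute_rules[[2]] <- list(source_entity = "gene", path = "@geneId",
                                   target_class = "orth:Gene",
                                   target_property = "orth:encodes")
  cfg <- bundle_config(b)
  expect_error(transform(b$schema, b$instances, bad, b$patterns, b$onto, cfg),
               "refuse-to-run")
})

test_that("stats are recomputable from the log and the knowledge base", {
  b <- gene_example()
  res <- run_bundle(b)
  lf <- log_frame(res$log)
  expect_equal(res$stats$individuals, length(res$kb$individuals))
  recomputed <- as.list(table(lf$action))
  expect_equal(res$stats$actions[order(names(res$stats$actions))],
               recomputed[order(names(recomputed))])
})

test_that("the external reasoner hook parses the verdict from the command output", {
  b <- gene_example()
  res <- run_bundle(b)
  cfg_yes <- bundle_config(b, reasoner_hook = c("sh", "-c",
                                                "echo consistent yes"))
  expect_true(invoke_reasoner(res$kb, cfg_yes))
  cfg_no <- bundle_config(b, reasoner_hook = c("sh", "-c",
                                               "echo consistent no"))
  expect_false(invoke_reasoner(res$kb, cfg_no))
  cfg_bad <- bundle_config(b, reasoner_hook = c("sh", "-c", "echo hmm"))
  expect_error(invoke_reasoner(res$kb, cfg_bad), "no verdict")
})
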