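## identity_engine: keys, resolution decisions, merging and sameAs linking

gene_setup <- function() {
  b <- gene_example()
  res <- run_bundle(b)
  rules <- ontoetl:::resolve_mapping(b$rules, b$onto)
  list(b = b, res = res, rule = rules$identity_rules[[1]])
}

test_that("the gene identity key combines the datatype and object property values", {
  s <- gene_setup()
  gene <- s$res$kb$individuals[["http://example.org/orthods/Gene/pyc-1"]]
  key <- identity_key(gene, s$rule, s$res$kb)
  expect_s3_class(key, "identity_key")
  expect_equal(key$class, "http://purl.org/net/orth#Gene")
  expect_setequal(key$tuple,
                  c("pyc-1", "http://example.org/orthods/organisms/6239"))
})

test_that("a missing identity property yields the incomplete signal, never a partial key", {
  s <- gene_setup()
  gene <- s$res$kb$individuals[["http://example.org/orthods/Gene/pyc-1"]]
  gene$objects <- gene$objects[gene$objects$property !=
                               "http://purl.obolibrary.org/obo/ro#in_taxon", ,
                               drop = FALSE]
  expect_identical(identity_key(gene, s$rule, s$res$kb), "incomplete")
})

test_that("byte-identical source records produce equal keys", {
  ## brute-force recomputation: build two individuals from the same record
  ## through independent code paths and compare the key tuples
  s <- gene_setup()
  kb <- s$res$kb
  gene <- kb$individuals[["http://example.org/orthods/Gene/pyc-1"]]
  clone <- individual("http://example.org/orthods/Gene/other-uri",
                      classes = gene$classes, data = gene$data,
                      objects = gene$objects,
                      provenance = gene$provenance)
  k1 <- identity_key(gene, s$rule, kb)
  k2 <- identity_key(clone, s$rule, kb)
  expect_identical(k1$tuple, k2$tuple)
})

test_that("a multi-valued identity property is an ambiguity error", {
  s <- gene_setup()
  gene <- s$res$kb$individuals[["http://example.org/orthods/Gene/pyc-1"]]
  gene$data <- rbind(gene$data, data.frame(
    property = "http://purl.org/net/orth#Identifier", value = "second",
    datatype = ontoetl:::xsd_uri("string"), stringsAsFactors = FALSE))
  expect_error(identity_key(gene, s$rule, s$res$kb), "ambiguity")
})

test_that("resolve_identity covers unique, merge, link and reject-incomplete", {
  s <- gene_setup()
  kb0 <- knowledge_base(s$b$onto)
  gene <- s$res$kb$individuals[["http://example.org/orthods/Gene/pyc-1"]]
  expect_equal(resolve_identity(gene, kb0, s$rule)$decision, "unique")

  clone <- gene; clone$uri <- "http://example.org/orthods/Gene/dup"
  dec <- resolve_identity(clone, s$res$kb, s$rule)
  expect_equal(dec$decision, "merge")
  expect_equal(dec$existing, gene$uri)

  link_rule <- s$rule; link_rule$behaviour <- "link"
  dec2 <- resolve_identity(clone, s$res$kb, link_rule)
  expect_equal(dec2$decision, "link")

  incomplete <- clone
  incomplete$data <- incomplete$data[0, , drop = FALSE]
  expect_equal(resolve_identity(incomplete, s$res$kb, s$rule)$decision,
               "reject-incomplete")
})

test_that("merging unions assertions and k duplicates leave one survivor", {
  onto <- tiny_onto()
  thing <- "http://example.org/t#Thing"
  rule <- identity_rule(thing, "http://example.org/t#name")
  mk <- function(i, name, extra = NULL) {
    ind <- individual(paste0("http://e.org/Thing/", i), classes = thing,
                      provenance = data.frame(source_id = "t", entity = "x",
                                              local_id = as.character(i),
                                              stringsAsFactors = FALSE))
    ind$data <- data.frame(property = "http://example.org/t#name",
                           value = name, datatype = ontoetl:::xsd_uri("string"),
                           stringsAsFactors = FALSE)
    if (!is.null(extra))
      ind$data <- rbind(ind$data, data.frame(
        property = "http://example.org/t#size", value = extra,
        datatype = ontoetl:::xsd_uri("integer"), stringsAsFactors = FALSE))
    ind
  }
  a <- mk(1, "alpha", "10")
  kb <- assert_axioms(knowledge_base(onto), axiom_batch(individuals = list(a)))
  b <- mk(2, "alpha", "20")
  m <- merge_individuals(kb, a$uri, b, rule)
  expect_true(m$ok)
  surv <- m$kb$individuals[[a$uri]]
  expect_setequal(surv$data$value[surv$data$property ==
                                  "http://example.org/t#size"], c("10", "20"))
  expect_equal(nrow(surv$provenance), 2L)
  expect_length(m$kb$individuals, 1L)

  ## brute-force grouping oracle over k duplicates
  set.seed(9)
  k <- 6L
  names_pool <- c("n1", "n2")
  inds <- lapply(seq_len(k), function(i) mk(i + 10, sample(names_pool, 1)))
  kb2 <- knowledge_base(onto)
  idx <- list()
  for (ind in inds) {
    dec <- resolve_identity(ind, kb2, rule, idx)
    if (dec$decision == "unique") {
      kb2 <- assert_axioms(kb2, axiom_batch(individuals = list(ind)))
      idx[[ontoetl:::key_string(dec$key)]] <- ind$uri
    } else {
      kb2 <- merge_individuals(kb2, dec$existing, ind, rule)$kb
    }
  }
  expected <- length(unique(vapply(inds, function(i) i$data$value[1],
                                   character(1))))
  expect_length(kb2$individuals, expected)
})

test_that("a merge that would clash on an identity property or disjointness aborts", {
  onto <- tiny_onto()
  thing <- "http://example.org/t#Thing"
  rule <- identity_rule(thing, "http://example.org/t#name")
  a <- individual("http://e.org/Thing/a", classes = thing,
                  provenance = data.frame(source_id = "t", entity = "x",
                                          local_id = "a",
                                          stringsAsFactors = FALSE))
  a$data <- data.frame(property = "http://example.org/t#name", value = "n",
                       datatype = ontoetl:::xsd_uri("string"),
                       stringsAsFactors = FALSE)
  kb <- assert_axioms(knowledge_base(onto), axiom_batch(individuals = list(a)))
  conflict <- a; conflict$uri <- "http://e.org/Thing/b"
  conflict$data$value <- "different"
  m <- merge_individuals(kb, a$uri, conflict, rule)
  expect_false(m$ok)
  expect_match(m$reason, "conflicting values")
  expect_identical(m$kb, kb)   # KB unchanged on abort

  disjoint_dup <- a; disjoint_dup$uri <- "http://e.org/Thing/c"
  disjoint_dup$classes <- c(thing, "http://example.org/t#Other")
  m2 <- merge_individuals(kb, a$uri, disjoint_dup, rule)
  expect_false(m2$ok)
  expect_match(m2$reason, "disjointness")
})

test_that("fresh-prefix merging re-mints the survivor under the configured prefix", {
  onto <- tiny_onto()
  thing <- "http://example.org/t#Thing"
  rule <- identity_rule(thing, "http://example.org/t#name",
                        merged_uri_policy = "fresh-prefix",
                        fresh_prefix = "http://example.org/merged/")
  mk <- function(u) {
    ind <- individual(u, classes = thing,
                      provenance = data.frame(source_id = "t", entity = "x",
                                              local_id = u,
                                              stringsAsFactors = FALSE))
    ind$data <- data.frame(property = "http://example.org/t#name", value = "n",
                           datatype = ontoetl:::xsd_uri("string"),
                           stringsAsFactors = FALSE)
    ind
  }
  a <- mk("http://e.org/Thing/a")
  kb <- assert_axioms(knowledge_base(onto), axiom_batch(individuals = list(a)))
  m <- merge_individuals(kb, a$uri, mk("http://e.org/Thing/b"), rule)
  expect_true(m$ok)
  expect_match(m$uri, "^http://example.org/merged/Thing/")
  expect_false(a$uri %in% names(m$kb$individuals))
})

test_that("linking retains both individuals, tolerates external URIs and self-links", {
  onto <- tiny_onto()
  a <- individual("http://e.org/Thing/a", classes = "http://example.org/t#Thing",
                  provenance = data.frame(source_id = "t", entity = "x",
                                          local_id = "a", stringsAsFactors = FALSE))
  kb <- assert_axioms(knowledge_base(onto), axiom_batch(individuals = list(a)))
  kb <- link_individuals(kb, a$uri, "http://purl.uniprot.org/uniprot/P63284")
  expect_equal(nrow(kb$same_as), 1L)
  expect_length(kb$individuals, 1L)
  expect_identical(link_individuals(kb, a$uri, a$uri), kb)  # self no-op
  kb$different_from <- rbind(c(a$uri, "http://e.org/Thing/z"))
  expect_error(link_individuals(kb, a$uri, "http://e.org/Thing/z"),
               "sameas-vs-differentfrom")
})

test_that("individuals minted with identical URIs are one individual regardless of identity rules", {
  ## two records with the same token and class produce the same URI; the
  ## engine unions them without consulting identity rules
  ddl <- "CREATE TABLE r (id VARCHAR PRIMARY KEY, tok VARCHAR, v VARCHAR);"
  csv <- "id,tok,v\nr1,K,x\nr2,K,y"
  mapping <- 'prefix ex <http://example.org/rec#>
entity r -> ex:Record
  token @tok
attribute r/@v -> ex:Record ex:value
'
  b <- ontoetl:::build_bundle("sameuri", "tabular",
    list(schema = ddl, data = list(r = csv), ontology = ontoetl:::REC_ONTO,
         mapping = mapping, patterns = list()),
    default_base = "http://example.org/recds/")
  res <- run_bundle(b)
  expect_length(res$kb$individuals, 1L)
  ind <- res$kb$individuals[[1]]
  expect_setequal(ind$data$value, c("x", "y"))
  expect_equal(nrow(ind$provenance), 2L)
})
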