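## ontology_kb: ontology loading, URI minting, axiom batches, the
## structural consistency check set, canonical serialization

test_that("the orthology ontology loads with its classes and object properties", {
  o <- load_ontology(ontoetl:::GENE_ONTO, "turtle")
  locals <- vapply(names(o$classes), ontoetl:::uri_local_name, character(1))
  expect_setequal(unname(locals), c("Gene", "Protein", "organisms", "database"))
  expect_true("http://purl.obolibrary.org/obo/ro#in_taxon" %in% names(o$oprops))
  expect_equal(o$dprops[[1]]$range, "http://www.w3.org/2001/XMLSchema#string")
})

test_that("an empty ontology document warns and a generated one reports its class count", {
  expect_warning(o <- load_ontology("", "turtle"), "empty ontology")
  expect_length(o$classes, 0L)
  for (k in c(1L, 7L, 23L)) {
    doc <- paste0("@prefix owl: <http://www.w3.org/2002/07/owl#> .\n",
                  "@prefix g: <http://example.org/g#> .\n",
                  paste0("g:C", seq_len(k), " a owl:Class .", collapse = "\n"))
    expect_length(load_ontology(doc, "turtle")$classes, k)
  }
})

test_that("RDF/XML ontologies load through the same model", {
  doc <- paste0('<?xml version="1.0"?>\n<rdf:RDF ',
    'xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
    'xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#" ',
    'xmlns:owl="http://www.w3.org/2002/07/owl#">\n',
    '<owl:Class rdf:about="http://example.org/g#A">',
    '<rdfs:label>A</rdfs:label></owl:Class>\n',
    '<owl:DatatypeProperty rdf:about="http://example.org/g#p">',
    '<rdfs:domain rdf:resource="http://example.org/g#A"/>',
    '<rdfs:range rdf:resource="http://www.w3.org/2001/XMLSchema#string"/>',
    '</owl:DatatypeProperty>\n</rdf:RDF>')
  o <- load_ontology(doc, "rdfxml")
  expect_length(o$classes, 1L)
  expect_length(o$dprops, 1L)
  expect_equal(o$dprops[[1]]$domain, "http://example.org/g#A")
})

test_that("mint_uri is deterministic, percent-encodes, and honours per-class policy", {
  pol <- uri_policy("http://example.org/ds/",
                    per_class_base = c("http://x#Protein" =
                                         "http://purl.uniprot.org/uniprot/"),
                    mode = c("http://x#Protein" = "adopt-external"))
  expect_equal(mint_uri(pol, "http://x#Protein", "P63284"),
               "http://purl.uniprot.org/uniprot/P63284")
  expect_equal(mint_uri(pol, "http://x#Gene", "pyc-1|6239"),
               paste0("http://example.org/ds/Gene/", "pyc-1%7C6239"))
  expect_identical(mint_uri(pol, "http://x#Gene", "a b"),
                   mint_uri(pol, "http://x#Gene", "a b"))
  expect_error(mint_uri(pol, "http://x#Gene", ""), "empty token")
  toks <- paste0("t", seq_len(1000L))
  uris <- vapply(toks, function(t) mint_uri(pol, "http://x#Gene", t),
                 character(1))
  expect_equal(length(unique(uris)), 1000L)
})

mk_ind <- function(uri, cls, onto) individual(
  uri, classes = cls,
  provenance = data.frame(source_id = "t", entity = "e", local_id = uri,
                          stringsAsFactors = FALSE))

test_that("assert_axioms is idempotent and order-independent", {
  onto <- tiny_onto()
  kb <- knowledge_base(onto)
  thing <- "http://example.org/t#Thing"
  a <- mk_ind("http://example.org/tds/Thing/a", thing, onto)
  b <- mk_ind("http://example.org/tds/Thing/b", thing, onto)
  batch <- axiom_batch(
    individuals = list(a, b),
    data = data.frame(subject = a$uri, property = "http://example.org/t#name",
                      value = c("x", "y"), datatype = ontoetl:::xsd_uri("string"),
                      stringsAsFactors = FALSE),
    objects = data.frame(subject = a$uri, property = "http://example.org/t#near",
                         object = b$uri, external = FALSE,
                         stringsAsFactors = FALSE))
  kb1 <- assert_axioms(kb, batch)
  expect_length(kb1$individuals, 2L)
  expect_equal(nrow(kb1$individuals[[a$uri]]$data), 2L)
  kb2 <- assert_axioms(kb1, batch)
  expect_identical(kb1, kb2)
  ## splitting the batch arbitrarily and applying in any order gives the
  ## same KB as the union applied at once
  set.seed(5)
  for (rep in 1:5) {
    parts <- list(
      axiom_batch(individuals = list(a, b)),
      axiom_batch(data = batch$data[sample(1:2), , drop = FALSE]),
      axiom_batch(objects = batch$objects))
    ord <- c(1L, sample(2:3))
    kbx <- kb
    for (i in ord) kbx <- assert_axioms(kbx, parts[[i]])
    expect_identical(kbx, kb1)
  }
})

test_that("undeclared terms in a batch are named in the error", {
  kb <- knowledge_base(tiny_onto())
  bad <- mk_ind("http://example.org/tds/X/1", "http://example.org/t#Nope", NULL)
  expect_error(assert_axioms(kb, axiom_batch(individuals = list(bad))),
               "unknown-term.*Nope")
})

test_that("the structural check set flags disjointness, ranges and sameAs clashes", {
  onto <- tiny_onto()
  both <- mk_ind("http://example.org/tds/Thing/d",
                 c("http://example.org/t#Thing", "http://example.org/t#Other"),
                 onto)
  kb <- knowledge_base(onto, individuals = setNames(list(both), both$uri))
  rep1 <- check_consistency(kb)
  expect_equal(rep1$kind, "disjointness")

  bad <- mk_ind("http://example.org/tds/Thing/e", "http://example.org/t#Thing",
                onto)
  bad$data <- data.frame(property = "http://example.org/t#size",
                         value = "not-an-int",
                         datatype = ontoetl:::xsd_uri("integer"),
                         stringsAsFactors = FALSE)
  kb2 <- knowledge_base(onto, individuals = setNames(list(bad), bad$uri))
  expect_equal(check_consistency(kb2)$kind, "datatype-range")

  a <- "http://example.org/tds/Thing/a"; b <- "http://example.org/tds/Thing/b"
  ## the constructor itself refuses the direct clash
  expect_error(knowledge_base(onto, same_as = rbind(c(a, b)),
                              different_from = rbind(c(b, a))),
               "share a pair")
  ## the clash through the closure is a violation, not a constructor error
  c_ <- "http://example.org/tds/Thing/c"
  kb4 <- knowledge_base(onto, same_as = rbind(c(a, b), c(b, c_)),
                        different_from = rbind(c(a, c_)))
  expect_equal(check_consistency(kb4)$kind, "sameas-vs-differentfrom")
})

test_that("a candidate batch is checked over KB plus candidate without mutation", {
  onto <- tiny_onto()
  a <- mk_ind("http://example.org/tds/Thing/a", "http://example.org/t#Thing", onto)
  kb <- assert_axioms(knowledge_base(onto), axiom_batch(individuals = list(a)))
  cand <- axiom_batch(class_assert = list(
    list(subject = a$uri, class = "http://example.org/t#Other")))
  rep <- check_consistency(kb, cand)
  expect_equal(rep$kind, "disjointness")
  expect_equal(nrow(check_consistency(kb)), 0L)  # KB untouched
})

test_that("consistency is monotone: an admissible union implies an admissible KB", {
  set.seed(13)
  onto <- tiny_onto()
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    inds <- lapply(seq_len(n), function(i)
      mk_ind(paste0("http://example.org/tds/Thing/m", i),
             "http://example.org/t#Thing", onto))
    kb <- assert_axioms(knowledge_base(onto),
                        axiom_batch(individuals = inds[-n]))
    batch <- axiom_batch(individuals = inds[n])
    if (nrow(check_consistency(kb, batch)) == 0L)
      expect_equal(nrow(check_consistency(kb)), 0L)
  }
})

test_that("an empty KB serializes to prefix declarations only", {
  kb <- knowledge_base(tiny_onto())
  doc <- serialize_kb(kb, "turtle", "rdf")
  lines <- strsplit(doc, "\n")[[1]]
  expect_true(all(grepl("^@prefix|^$", lines)))
})

test_that("equal KBs serialize byte-identically regardless of construction order", {
  onto <- tiny_onto()
  a <- mk_ind("http://example.org/tds/Thing/a", "http://example.org/t#Thing", onto)
  b <- mk_ind("http://example.org/tds/Thing/b", "http://example.org/t#Thing", onto)
  d1 <- data.frame(subject = a$uri, property = "http://example.org/t#name",
                   value = c("x", "y"), datatype = ontoetl:::xsd_uri("string"),
                   stringsAsFactors = FALSE)
  kb1 <- assert_axioms(knowledge_base(onto),
                       axiom_batch(individuals = list(a, b), data = d1))
  kb2 <- assert_axioms(knowledge_base(onto),
                       axiom_batch(individuals = list(b, a),
                                   data = d1[2:1, , drop = FALSE]))
  expect_identical(serialize_kb(kb1, "turtle", "rdf"),
                   serialize_kb(kb2, "turtle", "rdf"))
})

test_that("serialize -> load -> serialize is a fixed point, with expressions and links", {
  m <- molecule_example()
  r <- run_bundle(m)
  kb <- r$kb
  kb <- link_individuals(kb, names(kb$individuals)[1],
                         "http://purl.example.org/external/1")
  for (profile in c("rdf", "owl")) {
    t1 <- serialize_kb(kb, "turtle", profile)
    t2 <- serialize_kb(load_kb(t1, m$onto), "turtle", profile)
    expect_identical(t1, t2)
  }
})

test_that("every emitted subject URI is an absolute HTTP URI", {
  r <- run_bundle(gene_example())
  tr <- ontoetl:::kb_to_triples(r$kb, "owl")
  expect_true(all(grepl("^https?://", tr$s)))
})

test_that("serialization refuses a KB with violations unless overridden", {
  onto <- tiny_onto()
  both <- mk_ind("http://example.org/tds/Thing/d",
                 c("http://example.org/t#Thing", "http://example.org/t#Other"),
                 onto)
  kb <- knowledge_base(onto, individuals = setNames(list(both), both$uri))
  expect_error(serialize_kb(kb, "turtle", "rdf"), "refuse-to-serialize")
  expect_silent(serialize_kb(kb, "turtle", "rdf", override = TRUE))
})

test_that("the independent RDF parser agrees on both serialization formats", {
  m <- molecule_example()
  r <- run_bundle(m)
  count_with_rdflib <- function(path, fmt) {
    out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
      "import rdflib,sys; g=rdflib.Graph(); g.parse(sys.argv[1], format='",
      fmt, "'); print(len(g))")), path), stdout = TRUE, stderr = TRUE))
    as.integer(out[length(out)])
  }
  f1 <- tempfile(fileext = ".ttl")
  writeLines(serialize_kb(r$kb, "turtle", "owl"), f1, sep = "")
  f2 <- tempfile(fileext = ".rdf")
  writeLines(serialize_kb(r$kb, "rdfxml", "owl"), f2, sep = "")
  n1 <- count_with_rdflib(f1, "turtle")
  n2 <- count_with_rdflib(f2, "xml")
  expect_equal(n1, n2)
  expect_equal(n1, nrow(parse_turtle(paste(readLines(f1), collapse = "\n"))))
})
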