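## mapping_rules: dialect parsing, validation, condition semantics, the
## three basic rule applications

test_that("the dialect parser materializes entity and attribute rules", {
  rs <- parse_mapping_document(
    'prefix orth <http://purl.org/net/orth#>

entity gene -> orth:Gene
  token @geneId

attribute gene/@geneId -> orth:Gene orth:Identifier
')
  expect_length(rs$entity_rules, 1L)
  expect_length(rs$attribute_rules, 1L)
  expect_equal(rs$entity_rules[[1]]$source_entity, "gene")
  expect_equal(rs$entity_rules[[1]]$uri_token_path, "@geneId")
  expect_equal(rs$attribute_rules[[1]]$path, "@geneId")
})

test_that("a conditional entity rule carries its condition", {
  rs <- parse_mapping_document(
    'entity molecule -> Molecule
  when property[@name="isChiral"]/val eq "1"
')
  cond <- rs$entity_rules[[1]]$condition
  expect_s3_class(cond, "rule_condition")
  expect_equal(cond$attribute_path, 'property[@name="isChiral"]/val')
  expect_equal(cond$comparator, "eq")
  expect_equal(cond$literal, "1")
})

test_that("an empty document yields an empty rule set and syntax errors name lines", {
  rs <- parse_mapping_document("")
  expect_length(rs$entity_rules, 0L)
  expect_length(rs$attribute_rules, 0L)
  expect_error(parse_mapping_document("entity broken"), "line 1")
  expect_error(parse_mapping_document("entity a -> X\n  bogus opt"),
               "unknown entity option")
})

test_that("validation flags an attribute rule targeting an object property", {
  onto <- tiny_onto()
  sch <- load_tabular_schema("CREATE TABLE thing (id VARCHAR PRIMARY KEY);")
  rs <- parse_mapping_document(
    'prefix t <http://example.org/t#>
entity thing -> t:Thing
attribute thing/id -> t:Thing t:near
')
  rep <- validate_mapping(rs, sch, onto)
  expect_true("not-a-datatype-property" %in% rep$kind)
})

test_that("validation flags a relation rule whose entity rules are missing", {
  onto <- tiny_onto()
  sch <- suppressWarnings(load_tabular_schema(
    "CREATE TABLE a (id VARCHAR PRIMARY KEY);
     CREATE TABLE b (id VARCHAR PRIMARY KEY, a_id VARCHAR,
       FOREIGN KEY (a_id) REFERENCES a (id));"))
  rs <- parse_mapping_document(
    'prefix t <http://example.org/t#>
entity b -> t:Thing
relation b b_a_id a -> t:Thing t:near t:Thing
')
  rep <- validate_mapping(rs, sch, onto)
  expect_true("missing-entity-rule" %in% rep$kind)
})

test_that("the gene fixture mapping validates cleanly against its schema and ontology", {
  b <- gene_example()
  rep <- validate_mapping(b$rules, b$schema, b$onto, b$patterns)
  expect_equal(nrow(rep), 0L)
})

test_that("conditions are existential with coercion-failure-as-non-match", {
  mol <- function(val) data_instance("molecule", "M", list(
    name = "molecule", attrs = c(id = "M"), text = NA_character_,
    children = list(list(name = "property", attrs = c(name = "isChiral"),
                         text = NA_character_,
                         children = list(list(name = "val", attrs = character(0),
                                              text = val, children = list()))))))
  cond <- rule_condition('property[@name="isChiral"]/val', "eq", "1")
  expect_true(as.logical(evaluate_condition(cond, mol("1"))))
  expect_false(as.logical(evaluate_condition(cond, mol("0"))))
  no_path <- data_instance("molecule", "M", list(name = "molecule",
                                                 attrs = character(0),
                                                 text = NA_character_,
                                                 children = list()))
  expect_false(as.logical(evaluate_condition(cond, no_path)))
  num <- rule_condition("size", "gt", "10", "integer")
  multi <- data_instance("x", "1", list(
    name = "x", attrs = character(0), text = NA_character_,
    children = list(
      list(name = "size", attrs = character(0), text = "abc", children = list()),
      list(name = "size", attrs = character(0), text = "12", children = list()))))
  r <- evaluate_condition(num, multi)
  expect_true(as.logical(r))           # any value matches
  expect_match(attr(r, "warnings"), "coercion failure")
  expect_error(rule_condition("size", "lt", "x", "text"), "numeric")
})

resolved_gene_rules <- function(b) ontoetl:::resolve_mapping(b$rules, b$onto)

test_that("apply_entity_rule mints the congruent individual or signals a skip", {
  b <- gene_example()
  rules <- resolved_gene_rules(b)
  kb <- knowledge_base(b$onto)
  cfg <- bundle_config(b)
  gene <- Filter(function(i) i$entity == "gene", b$instances)[[1]]
  ind <- apply_entity_rule(rules$entity_rules[[1]], gene, kb, cfg$uri_policy)
  expect_s3_class(ind, "individual")
  expect_equal(ind$classes, "http://purl.org/net/orth#Gene")
  expect_equal(ind$uri, "http://example.org/orthods/Gene/pyc-1")
  expect_equal(ind$provenance$local_id, gene$local_id)
  cond_rule <- rules$entity_rules[[1]]
  cond_rule$condition <- rule_condition("@geneId", "eq", "something-else")
  expect_null(apply_entity_rule(cond_rule, gene, kb, cfg$uri_policy))
})

test_that("n passing instances yield n distinct-URI individuals", {
  b <- gene_example()
  rules <- resolved_gene_rules(b)
  kb <- knowledge_base(b$onto)
  cfg <- bundle_config(b)
  base <- Filter(function(i) i$entity == "gene", b$instances)[[1]]
  uris <- vapply(1:20, function(k) {
    ins <- base
    ins$tree$attrs["geneId"] <- paste0("g", k)
    apply_entity_rule(rules$entity_rules[[1]], ins, kb, cfg$uri_policy)$uri
  }, character(1))
  expect_length(unique(uris), 20L)
})

test_that("attribute rules keep the source lexical form and count multi-valued paths", {
  b <- gene_example()
  rules <- resolved_gene_rules(b)
  gene <- Filter(function(i) i$entity == "gene", b$instances)[[1]]
  ind <- individual("http://example.org/orthods/Gene/pyc-1",
                    classes = "http://purl.org/net/orth#Gene")
  da <- apply_attribute_rule(rules$attribute_rules[[1]], gene, ind, b$onto)
  expect_equal(nrow(da), 1L)
  expect_identical(da$value, "pyc-1")   # value fidelity, exact lexical form
  ## absent attribute: no assertion
  bare <- gene; bare$tree$attrs <- bare$tree$attrs[
    setdiff(names(bare$tree$attrs), "geneId")]
  expect_equal(nrow(apply_attribute_rule(rules$attribute_rules[[1]], bare,
                                         ind, b$onto)), 0L)
  ## multi-valued: k values -> k assertions (oracle: resolve_path length)
  onto <- tiny_onto()
  rule <- list(source_entity = "x", path = "tag",
               class_uri = "http://example.org/t#Thing",
               property_uri = "http://example.org/t#name")
  for (k in c(2L, 5L)) {
    ins <- data_instance("x", "1", list(
      name = "x", attrs = character(0), text = NA_character_,
      children = lapply(seq_len(k), function(i)
        list(name = "tag", attrs = character(0), text = paste0("v", i),
             children = list()))))
    expect_equal(nrow(apply_attribute_rule(rule, ins,
      individual("http://e.org/x/1"), onto)),
      length(resolve_path(ins, "tag")))
  }
})

test_that("range-violating values are withheld with a log entry", {
  onto <- tiny_onto()
  rule <- list(source_entity = "x", path = "sz",
               class_uri = "http://example.org/t#Thing",
               property_uri = "http://example.org/t#size")  # integer range
  ins <- data_instance("x", "1", list(
    name = "x", attrs = character(0), text = NA_character_,
    children = list(list(name = "sz", attrs = character(0), text = "big",
                         children = list()))))
  da <- apply_attribute_rule(rule, ins, individual("http://e.org/x/1"), onto)
  expect_equal(nrow(da), 0L)
  expect_match(attr(da, "withheld"), "violates range")
})

test_that("relation rules link registered counterparts and withhold otherwise", {
  s1 <- simple_instance("a", "a1")
  s2 <- simple_instance("b", "b1")
  rule <- list(s1 = "a", r1 = "a_b", s2 = "b",
               t1_uri = "http://example.org/t#Thing",
               r2_uri = "http://example.org/t#near",
               t2_uri = "http://example.org/t#Thing")
  reg <- list()
  reg[[ontoetl:::registry_key("test", "a", "a1", rule$t1_uri)]] <- "http://e/a1"
  reg[[ontoetl:::registry_key("test", "b", "b1", rule$t2_uri)]] <- "http://e/b1"
  oa <- apply_relation_rule(rule, list(s1 = s1, s2 = s2), reg)
  expect_equal(oa$subject, "http://e/a1")
  expect_equal(oa$object, "http://e/b1")
  reg2 <- reg[1]
  miss <- apply_relation_rule(rule, list(s1 = s1, s2 = s2), reg2)
  expect_s3_class(miss, "rule_withheld")
  expect_match(miss$withheld, "b\\[b1\\]")
})
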