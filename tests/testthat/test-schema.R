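## schema_model: XSD/DDL readers, instance readers, path resolution

test_that("the orthology XSD yields the expected entity/attribute/relation structure", {
  sch <- load_xml_schema(ontoetl:::GENE_XSD)
  expect_setequal(names(sch$entities), c("species", "database", "gene"))
  expect_setequal(names(sch$entities$gene$attributes),
                  c("@id", "@geneId", "@protId"))
  expect_setequal(names(sch$relations), c("species_database", "database_gene"))
  expect_true(all(vapply(sch$relations, `[[`, character(1), "realization") ==
                  "xml-containment"))
  expect_equal(sch$entities$gene$attributes[["@id"]]$value_kind, "integer")
})

test_that("a minimal XSD with one empty complex element gives 1 entity, 0 attributes, 0 relations", {
  sch <- load_xml_schema(
    '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
       <xs:element name="thing"><xs:complexType/></xs:element>
     </xs:schema>')
  expect_length(sch$entities, 1L)
  expect_length(sch$entities$thing$attributes, 0L)
  expect_length(sch$relations, 0L)
})

## generator with independent bookkeeping: a random nesting chain/tree of
## E complex elements must produce E entities and E-1 containment relations
random_tree_xsd <- function(n) {
  mk <- function(names) {
    if (length(names) == 1L)
      return(paste0('<xs:element name="', names[1], '"><xs:complexType>',
                    '<xs:attribute name="id" type="xs:string"/>',
                    '</xs:complexType></xs:element>'))
    k <- sample(seq_len(length(names) - 1L), 1L)
    paste0('<xs:element name="', names[1], '"><xs:complexType><xs:sequence>',
           mk(names[1L + seq_len(k)]),
           if (k < length(names) - 1L) mk(names[-seq_len(k + 1L)]) else "",
           '</xs:sequence></xs:complexType></xs:element>')
  }
  paste0('<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">',
         mk(paste0("e", seq_len(n))), '</xs:schema>')
}

test_that("a generated E-entity tree XSD yields E entities and E-1 relations", {
  set.seed(11)
  for (n in c(2L, 5L, 9L)) {
    sch <- load_xml_schema(random_tree_xsd(n))
    expect_length(sch$entities, n)
    expect_length(sch$relations, n - 1L)
  }
})

test_that("unsupported XSD constructs are rejected by name", {
  expect_error(load_xml_schema(
    '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
       <xs:import namespace="urn:x"/>
       <xs:element name="a"><xs:complexType/></xs:element>
     </xs:schema>'), "unsupported-construct: xs:import")
  expect_error(load_xml_schema(
    '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
       <xs:element name="a" substitutionGroup="b"><xs:complexType/></xs:element>
     </xs:schema>'), "substitutionGroup")
})

test_that("DDL with a foreign key gives 2 entities, 1 foreign-key relation, recorded keys", {
  sch <- load_tabular_schema(
    "CREATE TABLE protein (ac VARCHAR PRIMARY KEY, name VARCHAR);
     CREATE TABLE gene (id VARCHAR PRIMARY KEY, protein_ac VARCHAR,
       FOREIGN KEY (protein_ac) REFERENCES protein (ac));")
  expect_setequal(names(sch$entities), c("protein", "gene"))
  expect_length(sch$relations, 1L)
  expect_equal(sch$relations[[1]]$realization, "foreign-key")
  expect_equal(sch$entities$protein$key_attribute, "ac")
})

test_that("a composite primary key leaves key_attribute unset with a warning", {
  expect_warning(
    sch <- load_tabular_schema(
      "CREATE TABLE m (a VARCHAR, b VARCHAR, PRIMARY KEY (a, b));"),
    "composite primary key")
  expect_null(sch$entities$m$key_attribute)
})

test_that("a dangling foreign key is an error", {
  expect_error(load_tabular_schema(
    "CREATE TABLE g (id VARCHAR PRIMARY KEY, x VARCHAR,
       FOREIGN KEY (x) REFERENCES nowhere (id));"),
    "dangling-reference")
})

test_that("a generated descriptor with T tables and F foreign keys round-trips the counts", {
  set.seed(7)
  for (rep in 1:3) {
    T <- sample(2:6, 1L)
    tables <- paste0("t", seq_len(T))
    fks <- 0L
    ddl <- vapply(seq_len(T), function(i) {
      fk <- if (i > 1L && stats::runif(1) < 0.7) {
        fks <<- fks + 1L
        paste0(", ref", i, " VARCHAR, FOREIGN KEY (ref", i, ") REFERENCES ",
               tables[i - 1L], " (id)")
      } else ""
      paste0("CREATE TABLE ", tables[i], " (id VARCHAR PRIMARY KEY", fk, ");")
    }, character(1))
    sch <- load_tabular_schema(paste(ddl, collapse = "\n"))
    expect_length(sch$entities, T)
    expect_length(sch$relations, fks)
  }
})

test_that("XML instances arrive in document order with containment links and attribute values", {
  b_schema <- load_xml_schema(ontoetl:::GENE_XSD)
  doc <- '<species name="Caenorhabditis elegans" NCBITaxId="6239">
            <database name="UniProt">
              <gene id="1" geneId="pyc-1" protId="O17732"/>
            </database>
          </species>'
  ins <- read_xml_instances(doc, b_schema)
  expect_length(ins, 3L)
  expect_equal(vapply(ins, `[[`, character(1), "entity"),
               c("species", "database", "gene"))
  gene <- ins[[3]]
  expect_equal(resolve_path(gene, "@protId"), "O17732")
  expect_equal(resolve_path(gene, "@geneId"), "pyc-1")
  db <- ins[[2]]
  expect_equal(db$links[[1]]$relation, "database_gene")
  expect_equal(db$links[[1]]$target_local_id, gene$local_id)
})

test_that("an empty document body yields an empty stream and n genes yield n instances", {
  sch <- load_xml_schema(
    '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
       <xs:element name="root"><xs:complexType><xs:sequence>
         <xs:element name="gene" maxOccurs="unbounded"><xs:complexType>
           <xs:attribute name="id" type="xs:string"/>
         </xs:complexType></xs:element>
       </xs:sequence></xs:complexType></xs:element>
     </xs:schema>')
  ## the wrapper itself is declared, so instances of it are expected; an
  ## empty body contributes no gene instances
  empty <- read_xml_instances("<root/>", sch)
  expect_equal(sum(vapply(empty, `[[`, character(1), "entity") == "gene"), 0L)
  for (n in c(1L, 4L, 10L)) {
    doc <- paste0("<root>", paste0('<gene id="g', seq_len(n), '"/>',
                                   collapse = ""), "</root>")
    ins <- read_xml_instances(doc, sch)
    genes <- Filter(function(i) i$entity == "gene", ins)
    expect_length(genes, n)
    expect_equal(vapply(genes, `[[`, character(1), "local_id"),
                 paste0("gene_", seq_len(n)))
    ## order stability: two reads agree
    expect_identical(ins, read_xml_instances(doc, sch))
  }
})

test_that("undeclared elements error in strict mode and are skipped with a log in lenient mode", {
  sch <- load_xml_schema(
    '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
       <xs:element name="root"><xs:complexType><xs:sequence>
         <xs:element name="a"><xs:complexType/></xs:element>
       </xs:sequence></xs:complexType></xs:element>
     </xs:schema>')
  doc <- "<root><a/><mystery/></root>"
  expect_error(read_xml_instances(doc, sch, strict = TRUE), "undeclared")
  ins <- read_xml_instances(doc, sch, strict = FALSE)
  expect_length(attr(ins, "read_log"), 1L)
})

test_that("tabular rows become instances, FK columns become links, empty cells vanish", {
  sch <- suppressWarnings(load_tabular_schema(
    "CREATE TABLE protein (ac VARCHAR PRIMARY KEY, name VARCHAR);
     CREATE TABLE gene (id VARCHAR PRIMARY KEY, protein_ac VARCHAR,
       FOREIGN KEY (protein_ac) REFERENCES protein (ac));"))
  rows <- list(
    protein = data.frame(ac = "P1", name = "alpha", stringsAsFactors = FALSE),
    gene = data.frame(id = c("g1", "g2"), protein_ac = c("P1", ""),
                      stringsAsFactors = FALSE))
  ins <- read_tabular_instances(rows, sch)
  expect_length(ins, 3L)
  g1 <- Filter(function(i) i$local_id == "g1", ins)[[1]]
  g2 <- Filter(function(i) i$local_id == "g2", ins)[[1]]
  expect_length(g1$links, 1L)
  expect_equal(g1$links[[1]]$target_local_id, "P1")
  expect_length(g2$links, 0L)
  expect_equal(resolve_path(g2, "protein_ac"), character(0))
})

test_that("duplicated primary keys error in strict mode and collapse in lenient mode", {
  sch <- load_tabular_schema("CREATE TABLE t (id VARCHAR PRIMARY KEY, v VARCHAR);")
  ## brute-force duplicate scan as the oracle
  set.seed(21)
  ids <- sample(sprintf("k%02d", 1:6), 10L, replace = TRUE)
  d <- sum(duplicated(ids))
  rows <- list(t = data.frame(id = ids, v = "x", stringsAsFactors = FALSE))
  expect_error(read_tabular_instances(rows, sch, strict = TRUE),
               "duplicate primary key")
  ins <- read_tabular_instances(rows, sch, strict = FALSE)
  expect_length(ins, length(ids) - d)
})

test_that("value-kind violations name the row and column", {
  sch <- load_tabular_schema("CREATE TABLE t (id VARCHAR PRIMARY KEY, n INTEGER);")
  rows <- list(t = data.frame(id = "a", n = "twelve", stringsAsFactors = FALSE))
  expect_error(read_tabular_instances(rows, sch), "row 1 column 'n'")
})

test_that("resolve_path handles predicates, attribute steps, absence and bad syntax", {
  mol <- data_instance("molecule", "M1", list(
    name = "molecule", attrs = c(id = "M1"), text = NA_character_,
    children = list(
      list(name = "property", attrs = c(name = "isChiral"), text = NA_character_,
           children = list(list(name = "val", attrs = character(0),
                                text = "1", children = list()))),
      list(name = "property", attrs = c(name = "mass"), text = NA_character_,
           children = list(list(name = "val", attrs = character(0),
                                text = "18.0", children = list()))))))
  expect_equal(resolve_path(mol, 'property[@name="isChiral"]/val'), "1")
  expect_equal(resolve_path(mol, 'property[@name="mass"]/val'), "18.0")
  expect_equal(resolve_path(mol, "@id"), "M1")
  expect_equal(resolve_path(mol, "property/val"), c("1", "18.0"))
  expect_equal(resolve_path(mol, "absent/thing"), character(0))
  bare <- data_instance("x", "1", list(name = "x", attrs = character(0),
                                       text = NA_character_, children = list()))
  expect_equal(resolve_path(bare, "@whatever"), character(0))
  expect_error(resolve_path(mol, "bad//step"), "path-syntax")
  expect_error(resolve_path(mol, "@a/b"), "attribute step must be final")
})
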