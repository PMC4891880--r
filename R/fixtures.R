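## fixtures: worked-example project bundles (orthology gene, chiral
## molecule, protein/CDS/transcript, UniProt linking) and seeded synthetic
## sources for integration experiments. Everything is generated in code;
## a bundle carries both the raw source texts and the parsed objects, so
## every reader in the package is exercised on its own fixtures.

build_bundle <- function(name, schema_kind, texts, source_id = name,
                         default_base = "http://example.org/ds/",
                         per_class = character(0), mode = character(0),
                         strict = TRUE) {
  schema <- if (schema_kind == "xml") load_xml_schema(texts$schema)
            else suppressWarnings(load_tabular_schema(texts$schema))
  onto <- load_ontology(texts$ontology, "turtle")
  rules <- parse_mapping_document(texts$mapping)
  patterns <- lapply(texts$patterns %||% list(), function(t) NULL)
  if (length(texts$patterns))
    patterns <- stats::setNames(
      lapply(names(texts$patterns), function(nm)
        parse_pattern(texts$patterns[[nm]], nm)),
      names(texts$patterns))
  instances <- if (schema_kind == "xml")
    read_xml_instances(texts$data, schema, source_id, strict = strict)
  else {
    rows <- lapply(texts$data, function(csv)
      utils::read.csv(text = csv, stringsAsFactors = FALSE,
                      colClasses = "character"))
    read_tabular_instances(rows, schema, source_id, strict = strict)
  }
  ## class-name keyed policy entries resolved to URIs
  pcb <- character(0); md <- character(0)
  for (cn in names(per_class)) {
    cu <- onto_lookup(onto, cn, "class", rules$prefixes)
    pcb[cu] <- per_class[[cn]]
    if (!is.null(mode[cn]) && !is.na(mode[cn])) md[cu] <- mode[[cn]]
  }
  policy <- uri_policy(default_base, per_class_base = pcb, mode = md)
  structure(list(name = name, schema_kind = schema_kind, texts = texts,
                 schema = schema, instances = instances, onto = onto,
                 rules = rules, patterns = patterns, policy = policy,
                 source_id = source_id),
            class = "project_bundle")
}

#' @export
print.project_bundle <- function(x, ...) {
  cat("<project_bundle> ", x$name, " (", x$schema_kind, "): ",
      length(x$instances), " instances, ", length(x$patterns),
      " patterns\n", sep = "")
  invisible(x)
}

#' Default run configuration for a bundle
#' @param bundle a `project_bundle`.
#' @param ... overrides passed to [run_config()].
#' @return a [run_config()].
#' @export
bundle_config <- function(bundle, ...) {
  args <- list(uri_policy = bundle$policy, ...)
  do.call(run_config, args)
}

#' Run a bundle through the transform engine
#' @param bundle a `project_bundle`.
#' @param ... overrides passed to [run_config()].
#' @return a `transform_result`.
#' @export
run_bundle <- function(bundle, ...) {
  transform(bundle$schema, bundle$instances, bundle$rules, bundle$patterns,
            bundle$onto, bundle_config(bundle, ...))
}

## ---- orthology gene worked example ----------------------------------------

GENE_XSD <- '<?xml version="1.0"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="species">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="database" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="gene" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="id" type="xs:integer"/>
                  <xs:attribute name="geneId" type="xs:string"/>
                  <xs:attribute name="protId" type="xs:string"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="name" type="xs:string"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="name" type="xs:string"/>
      <xs:attribute name="NCBITaxId" type="xs:string"/>
    </xs:complexType>
  </xs:element>
</xs:schema>'

GENE_ONTO <- '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix orth: <http://purl.org/net/orth#> .
@prefix ncbi: <http://purl.obolibrary.org/obo/NCBITaxon#> .
@prefix sio: <http://semanticscience.org/resource/> .
@prefix ro: <http://purl.obolibrary.org/obo/ro#> .

orth:Gene a owl:Class ; rdfs:label "Gene" .
orth:Protein a owl:Class ; rdfs:label "Protein" .
ncbi:organisms a owl:Class ; rdfs:label "organisms" .
sio:database a owl:Class ; rdfs:label "database" .
orth:Identifier a owl:DatatypeProperty ; rdfs:domain orth:Gene ;
    rdfs:range xsd:string .
orth:encodes a owl:ObjectProperty ; rdfs:domain orth:Gene ;
    rdfs:range orth:Protein .
ro:in_taxon a owl:ObjectProperty ; rdfs:domain orth:Gene ;
    rdfs:range ncbi:organisms .
orth:contained_in a owl:ObjectProperty ; rdfs:domain orth:Gene ;
    rdfs:range sio:database .
'

GENE_MAPPING <- 'prefix orth <http://purl.org/net/orth#>
prefix ncbi <http://purl.obolibrary.org/obo/NCBITaxon#>
prefix sio <http://semanticscience.org/resource/>
prefix ro <http://purl.obolibrary.org/obo/ro#>

entity gene -> orth:Gene
  token @geneId

entity gene -> orth:Protein
  token @protId

entity species -> ncbi:organisms
  token @NCBITaxId

entity database -> sio:database
  token @name

attribute gene/@geneId -> orth:Gene orth:Identifier

relation gene database_gene database -> orth:Gene orth:contained_in sio:database

identity orth:Gene
  properties orth:Identifier, ro:in_taxon
  behaviour merge
  merged-uri first-wins

bind gene_links
  var ?gene = gene : orth:Gene
  var ?protein = gene : orth:Protein
  var ?taxon = species : ncbi:organisms
'

GENE_LINKS_PATTERN <- '?gene: INDIVIDUAL
?protein: INDIVIDUAL
?taxon: INDIVIDUAL
BEGIN
ADD ?gene encodes ?protein,
ADD ?gene ro:in_taxon ?taxon
END;
'

#' The orthology gene worked example
#'
#' One species element (Caenorhabditis elegans, NCBITaxId 6239) containing
#' a UniProt database element containing a gene with geneId "pyc-1" and
#' protId "O17732". The mapping produces a Gene individual carrying the
#' Identifier "pyc-1" and object links encodes (to the Protein), ro:in_taxon
#' (to the organism) and contained_in (to the database); an identity rule
#' on Gene uses Identifier plus ro:in_taxon.
#'
#' @param include_species include the species container (dropping it makes
#'   the gene's identity key incomplete, demonstrating rejection).
#' @return a `project_bundle`.
#' @export
gene_example <- function(include_species = TRUE) {
  gene_xml <- '<gene id="1" geneId="pyc-1" protId="O17732"/>'
  data <- if (include_species)
    paste0('<species name="Caenorhabditis elegans" NCBITaxId="6239">\n',
           '  <database name="UniProt">\n    ', gene_xml,
           '\n  </database>\n</species>')
  else paste0('<database name="UniProt">\n  ', gene_xml, '\n</database>')
  mapping <- GENE_MAPPING
  if (!include_species) {
    ## without the species element the taxon binding cannot resolve;
    ## keep the mapping otherwise identical
    mapping <- GENE_MAPPING
  }
  build_bundle("gene-orthology", "xml",
               list(schema = GENE_XSD, data = data, ontology = GENE_ONTO,
                    mapping = mapping,
                    patterns = list(gene_links = GENE_LINKS_PATTERN)),
               default_base = "http://example.org/orthods/")
}

## ---- chiral molecule example ----------------------------------------------

MOL_XSD <- '<?xml version="1.0"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="molecules">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="molecule" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="property" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="val" type="xs:string"/>
                  </xs:sequence>
                  <xs:attribute name="name" type="xs:string"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="id" type="xs:string"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>'

MOL_ONTO <- '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix mol: <http://example.org/mol#> .

mol:Molecule a owl:Class ; rdfs:label "Molecule" .
mol:Atom a owl:Class ; rdfs:label "Atom" .
mol:Bond a owl:Class ; rdfs:label "Bond" .
mol:Chirality a owl:Class ; rdfs:label "Chirality" .
mol:has_chemical_property a owl:ObjectProperty ; rdfs:domain mol:Molecule ;
    rdfs:range mol:Chirality .
'

MOL_PATTERN <- '?chiralMolecule: INDIVIDUAL
BEGIN
ADD ?chiralMolecule instanceOf (Molecule and
has_chemical_property some Chirality)
END;
'

MOL_MAPPING <- 'prefix mol <http://example.org/mol#>

entity molecule -> mol:Molecule
  token @id

bind chiral_molecule
  var ?chiralMolecule = molecule : mol:Molecule
  when property[@name="isChiral"]/val eq "1"
'

#' The chiral molecule example: conditional pattern enrichment
#'
#' Molecules carry a property element named isChiral whose val is 0 or 1.
#' All molecules map to the Molecule class; the chirality pattern fires
#' only for val=1 molecules and asserts membership in
#' (Molecule and has_chemical_property some Chirality), materializing one
#' Chirality filler individual per chiral molecule.
#'
#' @param chiral_flags integer (0/1) vector, one molecule per element.
#' @return a `project_bundle`; the flags are kept in the `truth` attribute.
#' @export
molecule_example <- function(chiral_flags = c(1L, 0L, 1L)) {
  mols <- paste0(vapply(seq_along(chiral_flags), function(i) {
    paste0('  <molecule id="M', i, '">\n',
           '    <property name="isChiral"><val>', chiral_flags[i],
           '</val></property>\n  </molecule>')
  }, character(1)), collapse = "\n")
  data <- paste0("<molecules>\n", mols, "\n</molecules>")
  b <- build_bundle("chiral-molecules", "xml",
                    list(schema = MOL_XSD, data = data, ontology = MOL_ONTO,
                         mapping = MOL_MAPPING,
                         patterns = list(chiral_molecule = MOL_PATTERN)),
                    default_base = "http://example.org/molds/")
  attr(b, "truth") <- list(chiral_flags = chiral_flags)
  b
}

## ---- protein / CDS / transcript patterns -----------------------------------

PROT_ONTO <- '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix gp: <http://example.org/geneprod#> .

gp:Polypeptide a owl:Class ; rdfs:label "Polypeptide" .
gp:CDS a owl:Class ; rdfs:label "CDS" .
gp:Transcript a owl:Class ; rdfs:label "Transcript" .
gp:derives_from a owl:ObjectProperty ; rdfs:domain gp:Polypeptide ;
    rdfs:range gp:CDS .
gp:part_of a owl:ObjectProperty ; rdfs:domain gp:CDS ;
    rdfs:range gp:Transcript .
'

prot_xsd <- function(with_cds) {
  inner <- if (with_cds)
    paste0('<xs:element name="cds" maxOccurs="unbounded">\n',
           '<xs:complexType><xs:sequence>\n',
           '<xs:element name="transcript" maxOccurs="unbounded">\n',
           '<xs:complexType><xs:attribute name="id" type="xs:string"/>',
           '</xs:complexType>\n</xs:element>\n</xs:sequence>',
           '<xs:attribute name="id" type="xs:string"/></xs:complexType>\n',
           '</xs:element>')
  else
    paste0('<xs:element name="transcript" maxOccurs="unbounded">\n',
           '<xs:complexType><xs:attribute name="id" type="xs:string"/>',
           '</xs:complexType>\n</xs:element>')
  paste0('<?xml version="1.0"?>\n',
         '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">\n',
         '<xs:element name="proteins"><xs:complexType><xs:sequence>\n',
         '<xs:element name="protein" maxOccurs="unbounded">\n',
         '<xs:complexType><xs:sequence>\n', inner,
         '\n</xs:sequence><xs:attribute name="acc" type="xs:string"/>',
         '</xs:complexType>\n</xs:element>\n',
         '</xs:sequence></xs:complexType></xs:element>\n</xs:schema>')
}

#' The protein pattern examples: template reuse with and without CDS
#'
#' Two project bundles over the same gene-product ontology. The first
#' source stores the protein-cds-transcript chain explicitly and uses the
#' plain protein pattern; the second has only a direct protein-transcript
#' relation and uses the variant whose ?cds variable is generated with
#' create(?protein.RENDERING+_CDS), synthesizing one CDS individual per
#' protein with URI token `<protein token>_CDS`. Both yield structurally
#' identical assertion shapes.
#'
#' @param n number of proteins per bundle.
#' @return list(with_cds = bundle, without_cds = bundle).
#' @export
protein_pattern_examples <- function(n = 3L) {
  accs <- sprintf("P%02d", seq_len(n))
  with_xml <- paste0(
    "<proteins>\n",
    paste0(vapply(seq_len(n), function(i)
      paste0('  <protein acc="', accs[i], '">\n',
             '    <cds id="C', i, '"><transcript id="T', i,
             '"/></cds>\n  </protein>'), character(1)), collapse = "\n"),
    "\n</proteins>")
  without_xml <- paste0(
    "<proteins>\n",
    paste0(vapply(seq_len(n), function(i)
      paste0('  <protein acc="', accs[i], '">\n',
             '    <transcript id="T', i, '"/>\n  </protein>'),
      character(1)), collapse = "\n"),
    "\n</proteins>")
  with_map <- 'prefix gp <http://example.org/geneprod#>

entity protein -> gp:Polypeptide
  token @acc

entity cds -> gp:CDS
  token @id

entity transcript -> gp:Transcript
  token @id

bind protein_cds
  var ?protein = protein : gp:Polypeptide
  var ?cds = cds : gp:CDS
  var ?transcript = transcript : gp:Transcript
'
  without_map <- 'prefix gp <http://example.org/geneprod#>

entity protein -> gp:Polypeptide
  token @acc

entity transcript -> gp:Transcript
  token @id

bind protein_nocds
  var ?protein = protein : gp:Polypeptide
  var ?transcript = transcript : gp:Transcript
'
  pat_dir <- system.file("extdata", "patterns", package = "ontoetl")
  read_pat <- function(f) paste(readLines(file.path(pat_dir, f)), collapse = "\n")
  list(
    with_cds = build_bundle("protein-with-cds", "xml",
      list(schema = prot_xsd(TRUE), data = with_xml, ontology = PROT_ONTO,
           mapping = with_map,
           patterns = list(protein_cds = read_pat("protein_cds.oppl"))),
      default_base = "http://example.org/gpds/"),
    without_cds = build_bundle("protein-without-cds", "xml",
      list(schema = prot_xsd(FALSE), data = without_xml, ontology = PROT_ONTO,
           mapping = without_map,
           patterns = list(protein_nocds = read_pat("protein_nocds.oppl"))),
      default_base = "http://example.org/gpds/"))
}

#' Multiset of assertion shapes of a knowledge base
#'
#' A shape is an object assertion abstracted from URIs: (classes of the
#' subject, property, classes of the target). Used to compare outputs that
#' should be structurally identical while differing in URIs.
#'
#' @param kb a [knowledge_base()].
#' @return sorted character vector (one entry per object assertion).
#' @export
assertion_shapes <- function(kb) {
  shapes <- character(0)
  cls_of <- function(u) {
    ind <- kb$individuals[[u]]
    if (is.null(ind)) return("external")
    paste(c_sort(vapply(ind$classes, uri_local_name, character(1))),
          collapse = "+")
  }
  for (ind in kb$individuals) {
    for (i in seq_len(nrow(ind$objects)))
      shapes <- c(shapes, paste0(cls_of(ind$uri), " -",
                                 uri_local_name(ind$objects$property[i]),
                                 "-> ", cls_of(ind$objects$object[i])))
  }
  c_sort(shapes)
}

## ---- UniProt interoperability example --------------------------------------

UP_ONTO <- '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix up: <http://example.org/prot#> .

up:Protein a owl:Class ; rdfs:label "Protein" .
up:accession a owl:DatatypeProperty ; rdfs:domain up:Protein ;
    rdfs:range xsd:string .
'

#' The UniProt URI interoperability example
#'
#' A protein resource stores UniProt accession numbers. Two ways of
#' linking to UniProt: "redefine" adopts the external URI scheme
#' (http://purl.uniprot.org/uniprot/ + AC) as the individual's own URI;
#' "link" keeps a local URI and emits an owl:sameAs pair to the UniProt
#' URI.
#'
#' @param mode "redefine" or "link".
#' @param accessions character vector of accession numbers.
#' @return a `project_bundle`.
#' @export
protein_link_example <- function(mode = c("redefine", "link"),
                                 accessions = "P63284") {
  mode <- match.arg(mode)
  ddl <- "CREATE TABLE protein (\n  id VARCHAR PRIMARY KEY,\n  ac VARCHAR\n);"
  df_csv <- paste(c("id,ac",
                    paste0("prot", seq_along(accessions), ",", accessions)),
                  collapse = "\n")
  mapping <- 'prefix up <http://example.org/prot#>

entity protein -> up:Protein
  token @ac

attribute protein/@ac -> up:Protein up:accession
'
  if (mode == "link")
    mapping <- paste0(mapping,
      '\nlink protein -> <http://purl.uniprot.org/uniprot/>\n',
      '  token @ac\n  class up:Protein\n')
  per_class <- if (mode == "redefine")
    c(Protein = "http://purl.uniprot.org/uniprot/") else character(0)
  md <- if (mode == "redefine") c(Protein = "adopt-external") else character(0)
  build_bundle("uniprot-link", "tabular",
               list(schema = ddl, data = list(protein = df_csv),
                    ontology = UP_ONTO, mapping = mapping, patterns = list()),
               default_base = "http://example.org/protds/",
               per_class = per_class, mode = md)
}

## ---- seeded synthetic sources ----------------------------------------------

#' Specification of a synthetic source pair
#'
#' @param seed integer RNG seed; identical specs yield identical bundles.
#' @param n_entities records per source.
#' @param duplicate_rate fraction of records that repeat an earlier
#'   record's identity code within the same source.
#' @param missing_identity_rate fraction of records whose identity code is
#'   absent (moved to the alt_code column, from which a recovery pattern
#'   can restore it).
#' @param overlap number of identity codes shared between the two sources.
#' @param conflict_rate fraction of overlapping codes whose non-identity
#'   value differs between the sources.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 0L, n_entities = 100L, duplicate_rate = 0.2,
                           missing_identity_rate = 0, overlap = 30L,
                           conflict_rate = 0) {
  stopifnot(duplicate_rate >= 0, duplicate_rate <= 1,
            missing_identity_rate >= 0, missing_identity_rate <= 1,
            conflict_rate >= 0, conflict_rate <= 1,
            overlap <= n_entities)
  structure(list(seed = as.integer(seed), n_entities = as.integer(n_entities),
                 duplicate_rate = duplicate_rate,
                 missing_identity_rate = missing_identity_rate,
                 overlap = as.integer(overlap), conflict_rate = conflict_rate),
            class = "synthetic_spec")
}

REC_DDL <- paste0("CREATE TABLE record (\n  id VARCHAR PRIMARY KEY,\n",
                  "  code VARCHAR,\n  alt_code VARCHAR,\n  val VARCHAR\n);")

REC_ONTO <- '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix ex: <http://example.org/rec#> .

ex:Record a owl:Class ; rdfs:label "Record" .
ex:code a owl:DatatypeProperty ; rdfs:domain ex:Record ; rdfs:range xsd:string .
ex:value a owl:DatatypeProperty ; rdfs:domain ex:Record ; rdfs:range xsd:string .
'

REC_RECOVERY_PATTERN <- '?r: INDIVIDUAL
?c: CONSTANT
BEGIN
ADD ?r code ?c
END;
'

rec_mapping <- function(behaviour, with_recovery) {
  m <- paste0('prefix ex <http://example.org/rec#>

entity record -> ex:Record
  token @id

attribute record/@code -> ex:Record ex:code
attribute record/@val -> ex:Record ex:value

identity ex:Record
  properties ex:code
  behaviour ', behaviour, '
  merged-uri first-wins
')
  if (with_recovery)
    m <- paste0(m, '\nbind code_recovery\n  var ?r = record : ex:Record\n',
                '  constant ?c = record/@alt_code\n')
  m
}

df_to_csv <- function(df) {
  tc <- textConnection("csvout", "w", local = TRUE)
  utils::write.csv(df, tc, row.names = FALSE, quote = FALSE, na = "")
  close(tc)
  paste(csvout, collapse = "\n")
}

#' Generate a pair of synthetic sources sharing one ontology
#'
#' Emulates the recurring problems of data integration: within-source
#' redundancy (duplicate identity codes), cross-source overlap, records
#' with missing identity values, and value conflicts between sources. The
#' generator records its ground truth (per-row flags and expected counts)
#' so oracle tests can audit the engine's decisions.
#'
#' @param spec a [synthetic_spec()].
#' @param behaviour identity behaviour written into the mappings: "merge"
#'   or "link".
#' @param with_recovery include the pattern binding that restores a
#'   missing code from the alt_code column.
#' @return list(source1, source2) of `project_bundle`s plus a `truth`
#'   attribute: per-source row frames and expected counts.
#' @export
synthetic_pair <- function(spec, behaviour = c("merge", "link"),
                           with_recovery = FALSE) {
  behaviour <- match.arg(behaviour)
  with_seed(spec$seed, {
    n <- spec$n_entities
    n_dup <- round(spec$duplicate_rate * n)
    n_unique <- n - n_dup
    if (spec$overlap > n_unique)
      stop("overlap exceeds the number of unique records per source")
    shared <- sprintf("SHARED%04d", seq_len(spec$overlap))
    mk_source <- function(tag) {
      own <- sprintf("%s%04d", tag, seq_len(n_unique - spec$overlap))
      uniq <- c(shared, own)
      dup_of <- if (n_dup > 0L) sample(uniq, n_dup, replace = TRUE) else character(0)
      codes <- c(uniq, dup_of)
      ord <- sample(seq_len(n))
      codes <- codes[ord]
      is_dup <- c(rep(FALSE, n_unique), rep(TRUE, n_dup))[ord]
      missing <- stats::runif(n) < spec$missing_identity_rate
      data.frame(id = sprintf("%sR%04d", tag, seq_len(n)),
                 code = ifelse(missing, NA_character_, codes),
                 alt_code = ifelse(missing, codes, NA_character_),
                 true_code = codes, is_dup = is_dup, missing = missing,
                 stringsAsFactors = FALSE)
    }
    s1 <- mk_source("A")
    s2 <- mk_source("B")
    ## non-identity value: per code, per source; conflicts on a fraction of
    ## the shared codes
    conflicted <- shared[stats::runif(length(shared)) < spec$conflict_rate]
    val_for <- function(code, src) {
      if (src == 2L && code %in% conflicted) paste0("v2-", code)
      else paste0("v-", code)
    }
    s1$val <- vapply(s1$true_code, val_for, character(1), src = 1L)
    s2$val <- vapply(s2$true_code, val_for, character(1), src = 2L)

    emit_cols <- c("id", "code", "alt_code", "val")
    mapping <- rec_mapping(behaviour, with_recovery)
    patterns <- if (with_recovery)
      list(code_recovery = REC_RECOVERY_PATTERN) else list()
    b1 <- build_bundle("synthetic-A", "tabular",
                       list(schema = REC_DDL,
                            data = list(record = df_to_csv(s1[emit_cols])),
                            ontology = REC_ONTO, mapping = mapping,
                            patterns = patterns),
                       source_id = "synthetic-A",
                       default_base = "http://example.org/recds/")
    b2 <- build_bundle("synthetic-B", "tabular",
                       list(schema = REC_DDL,
                            data = list(record = df_to_csv(s2[emit_cols])),
                            ontology = REC_ONTO, mapping = mapping,
                            patterns = patterns),
                       source_id = "synthetic-B",
                       default_base = "http://example.org/recds/")
    complete1 <- if (with_recovery) s1$true_code else s1$true_code[!s1$missing]
    complete2 <- if (with_recovery) s2$true_code else s2$true_code[!s2$missing]
    truth <- list(
      source1 = s1, source2 = s2, shared_codes = shared,
      conflicted_codes = conflicted,
      expected = list(
        rows_per_source = n,
        rejected_incomplete = if (with_recovery) 0L
                              else sum(s1$missing) + sum(s2$missing),
        merge_individuals = length(unique(c(complete1, complete2))),
        link_individuals = length(complete1) + length(complete2),
        link_sameas_pairs = length(complete1) + length(complete2) -
          length(unique(c(complete1, complete2)))))
    out <- list(source1 = b1, source2 = b2)
    attr(out, "truth") <- truth
    out
  })
}

## ---- seeded consistency-injection projects ---------------------------------

CONS_ONTO <- '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix cx: <http://example.org/cons#> .

cx:Measurement a owl:Class ; rdfs:label "Measurement" .
cx:Artifact a owl:Class ; rdfs:label "Artifact" .
cx:Measurement owl:disjointWith cx:Artifact .
cx:count a owl:DatatypeProperty ; rdfs:domain cx:Measurement ;
    rdfs:range xsd:integer .
cx:label a owl:DatatypeProperty ; rdfs:domain cx:Measurement ;
    rdfs:range xsd:string .
'

CONS_CLASH_PATTERN <- '?x: INDIVIDUAL
BEGIN
ADD ?x instanceOf Artifact
END;
'

CONS_BADINT_PATTERN <- '?x: INDIVIDUAL
?v: CONSTANT
BEGIN
ADD ?x count ?v
END;
'

CONS_MAPPING <- 'prefix cx <http://example.org/cons#>

entity item -> cx:Measurement
  token @id

attribute item/@name -> cx:Measurement cx:label

bind clash_injection
  var ?x = item : cx:Measurement
  when @fault eq "clash"

bind badint_injection
  var ?x = item : cx:Measurement
  constant ?v = item/@badval
'

#' A seeded random project with injected consistency faults
#'
#' Items map to a Measurement class; a fraction of them are marked to
#' receive (via patterns) either membership in a class disjoint with
#' Measurement or an integer-ranged datatype value that is not an integer.
#' The consistency gate must discard exactly the faulted candidates.
#'
#' @param seed integer seed.
#' @param n number of items.
#' @param fault_rate probability an item carries a fault.
#' @return a `project_bundle` with a `truth` attribute holding per-item
#'   fault kinds ("none", "clash", "badint").
#' @export
consistency_project <- function(seed = 0L, n = 10L, fault_rate = 0.3) {
  with_seed(seed, {
    kinds <- sample(c("none", "clash", "badint"), n, replace = TRUE,
                    prob = c(1 - fault_rate, fault_rate / 2, fault_rate / 2))
    df <- data.frame(id = sprintf("I%03d", seq_len(n)),
                     name = paste0("item-", seq_len(n)),
                     fault = ifelse(kinds == "clash", "clash", NA_character_),
                     badval = ifelse(kinds == "badint", "not-a-number",
                                     NA_character_),
                     stringsAsFactors = FALSE)
    ddl <- paste0("CREATE TABLE item (\n  id VARCHAR PRIMARY KEY,\n",
                  "  name VARCHAR,\n  fault VARCHAR,\n  badval VARCHAR\n);")
    b <- build_bundle("consistency-faults", "tabular",
                      list(schema = ddl, data = list(item = df_to_csv(df)),
                           ontology = CONS_ONTO, mapping = CONS_MAPPING,
                           patterns = list(
                             clash_injection = CONS_CLASH_PATTERN,
                             badint_injection = CONS_BADINT_PATTERN)),
                      default_base = "http://example.org/consds/")
    attr(b, "truth") <- list(kinds = kinds)
    b
  })
}

## ---- bundle writing (for the command-line interface) ------------------------

#' Write a project bundle to a directory with a manifest
#'
#' @param bundle a `project_bundle`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  texts <- bundle$texts
  schema_file <- if (bundle$schema_kind == "xml") "schema.xsd" else "schema.sql"
  writeLines(texts$schema, file.path(dir, schema_file))
  if (bundle$schema_kind == "xml") {
    writeLines(texts$data, file.path(dir, "data.xml"))
    data_entry <- "data.xml"
  } else {
    data_entry <- list()
    for (tb in names(texts$data)) {
      fn <- paste0(tb, ".csv")
      writeLines(texts$data[[tb]], file.path(dir, fn))
      data_entry[[tb]] <- fn
    }
  }
  writeLines(texts$ontology, file.path(dir, "ontology.ttl"))
  writeLines(texts$mapping, file.path(dir, "mapping.map"))
  pat_entry <- list()
  if (length(texts$patterns)) {
    dir.create(file.path(dir, "patterns"), showWarnings = FALSE)
    for (pn in names(texts$patterns)) {
      fn <- file.path("patterns", paste0(pn, ".oppl"))
      writeLines(texts$patterns[[pn]], file.path(dir, fn))
      pat_entry[[pn]] <- fn
    }
  }
  manifest <- list(
    schema = schema_file, schema_kind = bundle$schema_kind,
    data = data_entry, ontology = "ontology.ttl",
    ontology_format = "turtle", mapping = "mapping.map",
    patterns = pat_entry,
    source_id = bundle$source_id,
    base_uri = bundle$policy$default_base,
    per_class_base = as.list(bundle$policy$per_class_base),
    adopt_external = names(bundle$policy$mode)[
      bundle$policy$mode == "adopt-external"],
    output = "out.ttl", format = "turtle", profile = "rdf",
    emit_different_from = FALSE, strict = TRUE, seed = 0L)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
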