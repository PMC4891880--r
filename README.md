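# ontoetl

Ontology-driven transformation and integration of heterogeneous data into
RDF/OWL.

Biomedical data live in XML files and relational tables whose schemas say
little about what the data *mean*. `ontoetl` is an extraction-
transformation-load engine for turning such sources into Linked-Open-Data
style RDF/OWL datasets in which an OWL ontology, not the storage schema,
provides the vocabulary. It is aimed at anyone who needs to publish or
integrate structured records (orthology databases, compound libraries,
clinical extracts) as logically admissible semantic datasets without
writing a one-off conversion script per resource.

## The method

Both XML Schemas and relational schemas are reduced to one
entity-attribute-relation view. Three kinds of declarative **mapping
rules** connect that view to an OWL ontology:

* `entity_rule(S, T)` — every instance *s* of schema entity *S* yields a
  congruent individual *t* of ontology class *T*; an optional boolean
  condition `entity_rule(S, T, c₁)` restricts the rule to instances
  satisfying *c₁* over an attribute;
* `attribute_rule((S, A₁), (T, A₂))` — the value of attribute *A₁* becomes
  a datatype-property assertion *A₂* on *t*, with the identical lexical
  form;
* `relation_rule((S₁, R₁, S₂), (T₁, R₂, T₂))` — a link between two source
  records becomes an object-property assertion between their individuals.

Where basic rules cannot express a transformation — multiple source
entities feeding one description, or enrichment content absent from the
source — **transformation patterns** apply: templates ⟨S, V⟩ of axiom
statements over variables in an OPPL2-like subset
(`ADD ?x instanceOf (Molecule and has_chemical_property some Chirality)`),
including `create(?protein.RENDERING+_CDS)` expressions that mint new
individuals from an existing individual's URI token.

**Identity rules** `identity_rule(C, IR)` declare the property set *IR*
that univocally identifies individuals of class *C*: individuals of *C*
with equal complete value tuples over *IR* denote the same entity and are
either merged into one individual or kept and connected with
`owl:sameAs`, per the rule's behaviour. Records whose key is incomplete
are rejected rather than risk inconsistency — unless a pattern supplies
the missing values first.

Every candidate individual passes a **consistency gate** (class
disjointness, datatype ranges, object-property domain/range,
sameAs/differentFrom clashes) before admission; inadmissible batches are
discarded whole and logged. Integration of several sources is the same
transformation run against one shared knowledge base, so identity rules
deduplicate across sources. Output is canonical Turtle or RDF/XML: equal
knowledge bases serialize byte-identically.

## A worked example

The bundled orthology example maps an OrthoXML-style fragment — a species
(*Caenorhabditis elegans*, NCBITaxId 6239) containing a UniProt database
entry containing a gene with `geneId="pyc-1"`, `protId="O17732"` — onto an
orthology ontology:

```r
library(ontoetl)
b <- gene_example()
res <- run_bundle(b)
res
#> <transform_result> 4 admitted individuals; KB holds 4 individuals, 0 sameAs pairs; 9 log records
res$kb$individuals[["http://example.org/orthods/Gene/pyc-1"]]
#> <individual> http://example.org/orthods/Gene/pyc-1
#>   classes: Gene
#>   1 data / 3 object assertions
```

The four individuals are the Gene, the Protein it encodes, the organism,
and the database. The Gene individual carries the Identifier value
`"pyc-1"` (from the attribute rule) and three object assertions —
`encodes` the Protein `O17732`, `ro:in_taxon` the organism `6239`, and
`contained_in` the database `UniProt` — produced by a relation rule and a
pattern whose variables bind across the document's containment links.
`check_congruence()` confirms each admitted individual is obtainable from
its source record and violates no ontology constraint.

Serializing prints canonical Turtle:

```r
cat(serialize_kb(res$kb, "turtle", "rdf"))
#> @prefix ncbi: <http://purl.obolibrary.org/obo/NCBITaxon#> .
#> ...
#> <http://example.org/orthods/Gene/pyc-1>
#>     ro:in_taxon <http://example.org/orthods/organisms/6239> ;
#>     orth:Identifier "pyc-1" ;
#>     orth:contained_in <http://example.org/orthods/database/UniProt> ;
#>     orth:encodes <http://example.org/orthods/Protein/O17732> ;
#>     a orth:Gene .
```

Two-source integration with identity-key deduplication:

```r
spec <- synthetic_spec(seed = 0, n_entities = 100, duplicate_rate = 0.2,
                       overlap = 30)
pair <- synthetic_pair(spec, "merge")
# 100 records per source, 80 unique codes each, 30 codes shared
# -> 80 + 80 - 30 = 130 merged individuals
```

## Command line

```sh
ontoetl fixtures gene --out proj/
ontoetl validate  --manifest proj/manifest.yaml
ontoetl transform --manifest proj/manifest.yaml --out out.ttl
ontoetl integrate --manifest multi.yaml --fail-on-discard
```

A manifest is one YAML file naming schema, data, ontology, mapping and
pattern files plus the run configuration, so a run is a reviewable,
reproducible artifact.

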