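## shared helpers: tiny schemas/ontologies built in code, and a runner for
## two-source integration experiments

tiny_onto <- function() {
  load_ontology('@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix t: <http://example.org/t#> .
t:Thing a owl:Class ; rdfs:label "Thing" .
t:Other a owl:Class ; rdfs:label "Other" .
t:Thing owl:disjointWith t:Other .
t:size a owl:DatatypeProperty ; rdfs:domain t:Thing ; rdfs:range xsd:integer .
t:name a owl:DatatypeProperty ; rdfs:domain t:Thing ; rdfs:range xsd:string .
t:near a owl:ObjectProperty ; rdfs:domain t:Thing ; rdfs:range t:Thing .
', "turtle")
}

tiny_policy <- function() uri_policy("http://example.org/tds/")

simple_instance <- function(entity = "thing", local_id = "x1",
                            attrs = c(id = "x1"), children = list()) {
  tree <- list(name = entity, attrs = attrs, text = NA_character_,
               children = children)
  data_instance(entity, local_id, tree, source_id = "test")
}

integrate_pair <- function(pair, patterns = NULL) {
  if (is.null(patterns))
    patterns <- if (length(pair$source1$patterns)) pair$source1$patterns
                else list()
  cfg <- bundle_config(pair$source1)
  integrate(list(
    list(schema = pair$source1$schema, instances = pair$source1$instances,
         rules = pair$source1$rules),
    list(schema = pair$source2$schema, instances = pair$source2$instances,
         rules = pair$source2$rules)),
    patterns, pair$source1$onto, cfg)
}
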