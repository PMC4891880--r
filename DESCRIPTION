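Package: ontoetl
Title: Ontology-Driven Transformation and Integration of Heterogeneous Data into RDF/OWL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ontology-driven extraction-transformation-load (ETL) engine that
    maps heterogeneous input data (XML documents and relational/tabular exports)
    onto an OWL ontology through declarative mapping rules, reusable ontology
    transformation patterns, and identity rules, producing logically admissible,
    deduplicated Linked-Open-Data-style RDF/OWL datasets. Entity, attribute and
    relation rules establish congruence between source instances and ontology
    individuals; patterns (an OPPL2-like template subset) create and enrich
    individuals; identity rules drive merge or owl:sameAs linkage of equivalent
    individuals within and across sources; a structural consistency gate discards
    inadmissible content before it enters the knowledge base. Includes canonical
    Turtle and RDF/XML serialization, worked-example fixtures, and seeded
    synthetic source generators for integration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    yaml,
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
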