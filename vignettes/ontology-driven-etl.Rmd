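---
title: "Ontology-driven ETL: the model behind ontoetl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven ETL: the model behind ontoetl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoetl)
```

## The transformation model

`ontoetl` treats an input source — an XML document collection or a set of
relational tables — as instances of a schema reduced to entities,
attributes and relations. An OWL ontology supplies the target vocabulary:
classes, datatype properties and object properties, with domains, ranges,
disjointness and a subclass order. The correctness relation between a
source record *s* and a generated individual *t* is *congruence*: *t* must
be obtainable from *s* by the declared mapping rules, and *t* must be
consistent with the ontology's axioms and with *s*'s data.
`check_congruence()` audits exactly this after a run: clause (a) verifies
that every applicable attribute and relation rule's source values appear
among the individual's assertions, clause (b) that the individual
participates in no structural violation.

A run executes in a fixed order. First all entity rules fire, producing
the candidate set *I* of new individuals. Second, the pattern statements
that create new individuals execute and their creations join *I*
(creating variables are identified from the pattern definitions: a
variable carrying a `create()` expression, or an unbound INDIVIDUAL
variable typed by an `instanceOf` statement). Then, per candidate: the
remaining pattern statements add enrichment content; attribute rules
assign datatype-property values; relation rules instantiate object
properties; and finally the identity rules are checked — a unique
candidate is admitted, an equivalent one is merged or linked according to
the rule's behaviour. The admission of each candidate is gated by the
consistency check over the knowledge base plus the candidate's whole
batch; a violating batch is discarded in its entirety and logged, never
partially admitted.

Relation rules fire only on relations declared in the schema; containment
chains are not collapsed transitively. Where a link spans several hops
(the orthology fixture's gene-to-species connection, with a database
element in between), a pattern is the intended mechanism: its variable
bindings locate related records by breadth-first search over the
instance link graph, which is also how patterns absorb structural
heterogeneity between sources. Object assertions whose target individual
does not exist yet at admission time are deferred to a second pass, so
document order cannot affect the result; assertions whose target was
merged away are rewritten to the surviving URI (logged), and assertions
to never-admitted targets are dropped (logged).

## Identity, merging and linking

An identity rule for class *C* names the property set *IR* whose value
tuple univocally identifies an individual of *C* (subclasses inherit the
rule). Keys are complete or absent: a record missing any *IR* value is
rejected rather than matched on a partial key, because a half-key match
could silently conflate distinct entities. A multi-valued *IR* property is
treated as an ambiguity error and the record rejected — silently picking
one value would hide a data problem. Patterns may supply missing *IR*
values (they execute before identity resolution), which is the supported
recovery route for sources that store an identifier under another field.

Object-property values inside keys are canonicalized through the
`owl:sameAs` closure representative (the lexicographically smallest member
of the component), so two records whose taxon individuals are linked
rather than merged still compare equal. This canonicalization is an
interpretation choice: nothing in the key definition dictates how
merely-linked targets compare, and the closure representative is the
weakest canonical form that makes linking and merging agree.

Merging unions classes, assertions and provenance onto the survivor.
Under `first-wins` the earlier URI survives (so source order decides URIs,
and only URIs — the keyed canonical form, in which each URI is replaced by
its identity key, is invariant under input permutations, and
`keyed_canonical()` exists precisely to test that). Under `fresh-prefix`
the merged individual is re-minted under a configured prefix plus a short
digest of its key. A merge that would put conflicting values on an
identity property, or make the knowledge base inconsistent, aborts: both
records then remain distinct, the duplicate is rejected, and the conflict
is logged. Linking is star-shaped — each new duplicate links to the
group's first-seen representative — giving the same closure as a clique
at linear cost, and `(group size − 1)` pairs per group.

Individuals minted with the same URI are the same individual by
definition; their assertions union without consulting identity rules at
all.

## The consistency gate

Full OWL 2 DL reasoning is deliberately out of the core. The built-in
check set is decidable, fast and covers the violations the transformation
itself can produce: class disjointness (direct and inherited through the
subclass order), datatype-property range conformance (lexical-form checks
for integer, decimal, boolean; anything passes string), object-property
domain and range as asserted-type checks (skipped when the property lacks
a declared domain/range or the target's classes are unknown, e.g. an
external URI), and sameAs/differentFrom clashes through the closure. A
pluggable external-reasoner hook (`invoke_reasoner()`) serializes the
knowledge base and parses a "consistent yes/no" verdict from any
command-line reasoner, for users who need the full semantics. Because
every check in the set is local to one subject individual, the gate
evaluates only the candidate batch's subjects against the growing
knowledge base, keeping admission linear in output size.

Anonymous class expressions are restricted to intersections of named
classes with existential restrictions (`C and P some D`) — the form
pattern enrichment needs. An existential restriction on an individual is
realized by minting one deterministic filler individual per subject
(token: subject token + "_" + property local name) plus the recorded
expression membership, emitted in the `owl` output profile. Materializing
the filler keeps the knowledge base ground and checkable without a
reasoner; the preserved expression membership lets a reasoner-hook user
verify the restriction properly. Whether a tool should materialize such
fillers at all is a genuine design choice; the deterministic token makes
the decision at least idempotent and auditable.

## URIs and serialization

Minted URIs follow `base + ClassLocalName + "/" + percent-encoded token`,
with the token taken from the entity rule's token path (falling back to
the record's local id, with a logged warning). A per-class policy can
instead adopt an external authority's scheme (`adopt-external`), which is
how a protein record with a UniProt accession gets
`http://purl.uniprot.org/uniprot/P63284` as its own URI; the alternative
is an `owl:sameAs` link to that URI, declared in the mapping. Which to
choose depends on whether per-source RDF versions of the data should
co-exist.

Serialization is canonical: subjects, predicates and objects are ordered
lexicographically by URI (C locale), literals after URIs, so set-equal
knowledge bases serialize byte-identically and serialize → load →
serialize is a fixed point. The `rdf` profile emits ground assertions and
sameAs links; `owl` adds expression memberships and (when enabled)
`owl:differentFrom`. differentFrom generation is off by default — the
axioms grow quadratically within a class and are only needed when
downstream reasoning requires explicit distinctness; when enabled they
are emitted pairwise within each identity-ruled class between individuals
with differing complete keys only, since the keys are the only warranted
distinctness criterion.

No RDF parsing library is available to this package in R, so the Turtle
reader is a purpose-built recursive-descent parser over the subset the
package writes plus ordinary ontology documents (prefix directives,
predicate-object lists, typed literals, blank-node property lists,
collections); the test suite cross-checks both writers against an
independent RDF parser.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `profile` | `run_config()` | `"rdf"` | ground output; `"owl"` adds expression memberships |
| `serialization` | `run_config()` | `"turtle"` | compact, diffable |
| `emit_different_from` | `run_config()` | `FALSE` | quadratic axiom growth; opt-in |
| `strict_reading` | `run_config()` | `TRUE` | silent data loss must be opt-in; lenient mode skips with a log |
| `behaviour` | identity rule | `merge` | deduplicated warehouse; `link` preserves per-source views |
| `merged-uri` | identity rule | `first-wins` | stable, no new URIs; `fresh-prefix` for neutral authorities |
| `random_seed` | `run_config()` | 0 | reserved for tie-breaking; the engine itself is deterministic |

Condition comparators include the orderings (`lt`, `le`, `gt`, `ge`)
restricted to numeric value kinds; equality on a single path is the
well-trodden case, the orderings are a conservative extension. Conditions
over multi-valued paths are existential — any matching value fires the
rule — and a coercion failure counts as a non-match with a logged
warning, never an abort.

## What the synthetic generator emulates — and what it does not

`synthetic_pair()` builds two tabular sources over one ontology with the
classic integration pathologies under explicit control: within-source
redundancy (`duplicate_rate` — a fraction of rows repeat an earlier row's
identity code), cross-source overlap (`overlap` shared codes),
incomplete identity data (`missing_identity_rate` — the code moves to an
`alt_code` column from which a recovery pattern can restore it), and
value conflicts on non-identity attributes (`conflict_rate`). The
generator records per-row ground truth, and every oracle quantity (unique
codes, expected rejections, expected sameAs pairs) is recomputable from
the emitted CSV alone, so tests audit the engine against bookkeeping the
engine never sees. `consistency_project()` likewise injects disjointness
clashes and datatype-range faults through patterns, with per-item fault
labels as ground truth.

What passing these tests shows: the engine's decisions (admit, merge,
link, reject, discard) match exact combinatorial oracles under controlled
conditions. What it does not show: behaviour on real data's messiness —
near-duplicate identifiers, inconsistent capitalization, genuinely
ambiguous identity, schema drift — none of which the generator produces.
The identity machinery is exact-match by design; probabilistic record
linkage is explicitly out of scope.

## Problem sizes and numerical choices

The bundled studies run at desk scale, chosen so the full suite and the
reproduction script complete in minutes on one core: the synthetic pair
uses 100 records per source (duplicate rate 0.2, overlap 30); the
fault-injection sweep uses 100 seeded projects of 10 items each (fault
rate 0.3); worked examples are single-figure. Counts, not statistics, are
asserted, so scale adds cost but no power here.

Degenerate inputs are defined rather than accidental: an empty instance
stream yields an empty knowledge base and an empty log; a path that
resolves to nothing is an empty result, not an error; an empty token for
URI minting is an error; an attribute value violating the target range is
withheld per-assertion (logged) by the attribute rule itself, while
violations arriving through pattern content are caught by the gate and
discard the candidate's whole batch. Composite primary keys yield no
key attribute — identity must then come from identity rules.

## Known limitations

* The structural check set under-approximates OWL 2 DL; content a full
  reasoner would reject (e.g. via property chains or cardinality) can
  pass the gate. The reasoner hook exists for that reason.
* XML support covers a single default namespace and an XML Schema subset
  (element/attribute declarations, sequences, inline complex types);
  imports, substitution groups and redefinition are rejected loudly.
* Static mapping validation checks single-step attribute paths against
  the schema; multi-step paths are checked syntactically only and
  resolve (or not) at run time.
* Identity resolution sees the assertions available when a candidate is
  admitted; an object-property identity value pointing at a
  later-admitted individual would read as incomplete. In practice parent
  records precede children in document order, and patterns run before
  identity, which covers the supported designs.
* Triplestore backends, SPARQL, archetype inputs and mapping
  recommendation are out of scope.
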