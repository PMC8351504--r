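---
title: "Representing and querying glycoconjugate data with glycocoo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing and querying glycoconjugate data with glycocoo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycocoo)
```

## The problem this package addresses

Glycoproteomics experiments report proteins together with the glycans
attached to them: which residue carries a glycan (the glycosylation site),
which glycan structures occupy it (glycoforms, referenced by GlyTouCan
accession), at what relative abundance, in which organism, tissue or cell
line the material originated, under which disease state, and in which
publication the observation appeared. Databases such as UniCarbKB, GlyConnect
and GlycoNAVI curate this information independently, and the GlycoCoO
ontology gives them a shared RDF vocabulary so that one SPARQL query can
retrieve and reconcile all three.

`glycocoo` is a working toolkit around that vocabulary. It builds
standards-conformant RDF descriptions of glycoconjugates into named-graph
datasets (one graph per source database), serializes them canonically in
Turtle/TriG/N-Quads, validates their structure, evaluates the five canned
integration queries (sites, glycans, diseases, publications, sources) with
the SERVICE clauses rewritten for offline use, and summarises cross-database
overlap. A seeded synthetic-data generator produces arbitrary-size conformant
datasets with ground-truth tables, which is how the query engine is tested.

## The data model

The central modelling idea, inherited from GlycoRDF, is the
*ReferencedCompound* pattern: a compound's identity (a glycan, a protein, a
conjugate) is kept separate from each evidence-bearing instance of it. One
`gco:ReferencedGlycoconjugate` node anchors one database's description of one
glycoprotein, and hangs off it:

* a protein part (`gco:has_protein_part`) typed `gco:ReferencedProtein`,
  whose protein reaches the UniProt accession through
  `rdfs:seeAlso`/`dcterms:identifier`, and which carries one FALDO region per
  glycosylation site (`gco:glycosylated_at` → `faldo:location` →
  `faldo:position`);
* saccharide parts (`gco:has_saccharide_part`), each reaching a GlyTouCan
  accession through `glycan:has_glycan` → `foaf:primaryTopicOf` →
  `dcterms:identifier`;
* a biological source (`glycan:is_from_source`) with a taxon and,
  independently optional, a tissue and a cell line;
* citations (`glycan:published_in`) carrying both `glycan:has_pmid` and
  `dcterms:references`;
* disease associations (`glycan:has_association` → `sio:SIO_000628`), whose
  disease nodes carry both an `rdfs:label` and a `skos:notation` code.

These chains are exactly the mandatory patterns of the five canned queries,
so everything a builder emits is retrievable by query, and the validator can
guarantee queryability (see below). Sites and glycans are deliberately
independent of each other: data with glycans but no site mapping (common when
no site-resolved experiment was performed) is representable and valid.

Two relations the ontology names but prints no predicate for live in a
dedicated extension namespace (`gcx:`, non-normative): glycan abundance
ratios (`gcx:has_abundance_ratio`, a decimal in [0, 1] on the saccharide-part
node) and lipid parts (`gcx:has_lipid_part`, a structural mirror of the
protein part for glycolipids; no lipid fixtures are shipped). The `skos`
namespace is the 2008 draft IRI (`http://www.w3.org/2008/05/skos#`) because
that is the namespace the published queries declare.

## Node minting and determinism

RDF instance IRIs for conjugates, parts, regions, sources, citations and
disease nodes are not standardized anywhere, so the package mints them
deterministically: a readable path under a configurable base (default
`http://glycoinfo.org/glycocoo/instance/`) composed from the graph's local
name, the UniProt accession, the element kind and its natural key (site
position, GlyTouCan accession, PMID, disease label). Consequences:

* building the same record twice is a no-op (triple sets deduplicate);
* the same (graph, record, element) always yields the same IRI across runs
  and sessions, so fixtures serialize byte-identically;
* no blank nodes are emitted, which keeps cross-serialization diffs
  meaningful.

Glycosylation positions are 1-based UniProt residue numbers stored as FALDO
exact positions (`xsd:integer`). Ranges are not supported: every position in
the source material is a single residue. Abundances are written as
`xsd:decimal` with at most six fractional digits; PMIDs as `xsd:integer`
(the publications query projects them through `str()`, so the typing is
safe).

## Canonical serialization

`write_dataset()` sorts graphs and triples bytewise by (graph, subject,
predicate, object), emits one triple per line, and restricts prefix
declarations to the package vocabulary. Writing is therefore deterministic,
and write→parse→write is a byte-level fixpoint. Turtle is accepted only for
a single graph (or an explicitly selected one); TriG and N-Quads carry the
full dataset. The parser accepts the usual Turtle abbreviations (`;`, `,`,
`a`, bare numbers, `@prefix`/`PREFIX`) and reports syntax errors with
line/column positions. `@base` and relative IRIs are deliberately
unsupported: every IRI in the toolkit is absolute, which is what keeps
canonical output stable. One test cross-checks the TriG writer against an
independent RDF library (Python's rdflib) on the haptoglobin fixture.

## Validation

The ontology ships no formal shapes, so `validate_dataset()` applies seven
structural rules reverse-engineered from the queries' mandatory patterns
(R1 protein part → protein; R2 protein → accession; R3 region → location →
position ≥ 1; R4 saccharide → GlyTouCan accession; R5 disease label+notation;
R6 citation PMID+reference; R7 conjugate has ≥ 1 protein or lipid part).
Patterns the queries wrap in OPTIONAL — tissue, cell line, taxon, organism
name — are exempt on purpose: validation guarantees queryability, not
completeness of metadata. A saccharide part without any site mapping is not
an error for the same reason. All rules are errors; there is no warning
tier, which keeps reports binary and testable. Reports list
(rule, graph, focus node, message) rows and are independent of triple
insertion order.

## Query evaluation and offline federation

`sparql_select()` implements the SPARQL 1.1 SELECT fragment the published
queries use: basic graph patterns with `;`/`,` abbreviations, `GRAPH`,
nested groups, `OPTIONAL` (left join with SPARQL compatibility semantics),
`UNION`, single-variable inline `VALUES`, `DISTINCT`, `str()` projection
expressions and `ORDER BY` (numeric literals sort numerically, unbound sorts
lowest). `FILTER`, `BIND`, `MINUS`, property paths and aggregation are out of
scope. The stored query texts are kept exactly as published, including their
quirks: a duplicated `dcterms` prefix line, reliance on an undeclared `rdfs`
prefix (the evaluator pre-binds `rdf`, `rdfs` and `xsd` when a query omits
them), and `str (?pmid)` with a space.

Federation is offline-first. `rewrite_service()` removes each
`SERVICE <endpoint>` wrapper whose endpoint has a local copy, leaving the
body (including its GRAPH patterns) to evaluate against the local dataset;
an unmapped endpoint is an error naming the IRI, unless passthrough is
requested for live federation. Because the rewrite only strips the SERVICE
indirection, local evaluation provably equals remote evaluation whenever the
local graphs equal the remote content, and the test suite asserts the
equality against hand-inlined queries.

Two design points were genuinely open:

* **Graph scope of the typed wrappers.** The published queries pin `?g` to
  the three database graphs with `VALUES`. The `run_*` wrappers widen those
  `VALUES` lists to the dataset's own named graphs so the same API works on
  any dataset (e.g. the single-graph worked example). On the three-database
  fixture this changes nothing: the UNION branches then overlap and
  `DISTINCT` collapses the duplicates.
* **The sources query's GlycoNAVI branch.** As published, it binds the
  protein chain through `?ref_conjugate`/`?ref_protein`, variables disjoint
  from the source pattern's `?glycoconjugate_ref`, which cross-joins when a
  graph holds several conjugates. The verbatim text is preserved
  (`canned_query("sources")`, `run_sources(..., verbatim = TRUE)`), but the
  typed wrapper defaults to a corrected variant with the variables unified,
  because only that variant satisfies row-for-row agreement with generated
  ground truth when graphs contain many proteins. On single-protein graphs
  the two variants agree.

`overlap_summary()` groups one result column by the set of graphs binding
each value and partitions values into common-to-all, shared-by-some and
unique-to-one; the partitions are disjoint and exhaustive, and with a single
graph in play everything is unique-to-one.

## Fixtures

`fixture_haptoglobin()` encodes the three-database description of
haptoglobin (UniProt P00738): per-graph site lists (GlyConnect
184/207/211/241, GlycoNAVI 184/207/211, UniCarbKB 184/187/207/211/241), four
GlyTouCan accessions (G22140GZ, G36131WL, G42358LZ, G62165AG) present in all
three graphs plus two unshared synthetic accessions per graph, esophageal
cancer shared by GlyConnect and UniCarbKB, hepatocellular carcinoma shared by
GlycoNAVI and GlyConnect plus one unshared cancer each for those two, Homo
sapiens as the organism everywhere, a cell line only in GlycoNAVI, a tissue
only in GlyConnect, and PMIDs overlapping only between UniCarbKB and
GlyConnect. Identifiers the integration account does not state — disease
notation codes, PMIDs, tissue/cell-line IRIs, the unshared accessions, the
worked example's glycan — are synthetic placeholders (notations `SYN:*`,
IRIs under `.../synthetic/`, PMIDs in the 9xxxxxxx range) chosen so that
every stated sharing pattern holds exactly; no invented value masquerades as
a curated one. `fixture_worked_example()` encodes the Q9EQH7 example with its
single annotated site at position 146.

## The synthetic generator

`synth_dataset()` draws `n_proteins` accessions, assigns each to a random
non-empty subset of the graphs, and per (protein, graph) draws sites, glycans
from a shared pool (so accessions recur across graphs and overlap partitions
are non-trivial), diseases, PMIDs, abundances, and a source. Everything is
emitted through the same builders users call, and everything drawn is
recorded in ground-truth tables shaped exactly like the `run_*` outputs —
the generator is the oracle for the query engine. Defaults follow the
desk-scale study conditions used throughout the tests: 20 proteins, 1–5
sites per record, 0–4 glycans per site, the three database graphs, all
metadata families on. One subtlety: records without an organism name use the
NCBI "unidentified" taxon rather than a named taxon, because taxon IRIs are
shared real-world nodes within a graph and a name attached by one record
must not leak into another record's expected rows.

The generator emulates the *structure* of curated glycoproteomics data, not
its content: accessions, codes and IRIs are synthetic; site positions are
uniform over 1–600 rather than sequence-motif-constrained; abundances are
uniform rather than compositional; and the generator never produces the
malformed input real curation pipelines see. Passing the oracle tests
therefore demonstrates that the builders, serializers and query engine are
mutually consistent and lossless — not that any biological claim holds.

## Problem sizes and runtime

The test suite and acceptance script run at desk scale, chosen so the whole
suite completes in about a minute on one core: the haptoglobin fixture
(~200 triples), oracle equivalence at 20 proteins × 3 graphs (~2,000
triples, 100 query evaluations), 100 small random datasets for round-trip
identity, and exhaustive single-triple deletion over the fixture's
query-critical chains for validator sensitivity. The engine is pure R with
set-semantics joins; it is comfortable to a few tens of thousands of triples
and makes no attempt at triplestore-scale performance.

## Known limitations

* SPARQL coverage is the fragment above; arbitrary user queries using
  `FILTER` or property paths are rejected with a clear error.
* RDF/XML and JSON-LD are not read or written; blank nodes are accepted on
  parse but never minted.
* Live SERVICE federation is opt-in passthrough only; the package never
  contacts the network itself.
* No OWL reasoning: `rdf:type` assertions are emitted for the three
  ReferencedCompound subclasses but subclass inference is not applied.
* Glycan structures are referenced by accession only; sequence formats and
  structure-relationship analysis are out of scope.
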