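# glycocoo

An R toolkit for the **GlycoCoO glycoconjugate ontology**: build, validate,
serialize and query standards-conformant RDF descriptions of glycoproteins
and glycolipids — glycosylation sites, GlyTouCan-referenced glycans and their
abundance ratios, biological sources, disease associations and citations —
and reconcile the descriptions that different databases publish for the same
protein.

It is written for glycoproteomics database maintainers and bioinformaticians
who want to emit GlycoCoO-conformant RDF from tabular curation output, check
that existing RDF is structurally queryable, and run the standard
cross-database integration queries without hosting or contacting live SPARQL
endpoints.

## The model in brief

GlycoCoO follows the GlycoRDF *ReferencedCompound* pattern: the identity of a
compound is separated from each evidence-bearing instance of it. One
`gco:ReferencedGlycoconjugate` node per (database, glycoprotein) anchors:

```
conjugate ─ gco:has_protein_part ─ part ─ gco:has_protein ─ protein
                                   │          └ rdfs:seeAlso ─ xref ─ dcterms:identifier ─ "P00738"
                                   └ gco:glycosylated_at ─ region ─ faldo:location ─ loc ─ faldo:position ─ 184
          ─ gco:has_saccharide_part ─ part ─ glycan:has_glycan ─ saccharide
                                               └ foaf:primaryTopicOf ─ xref ─ dcterms:identifier ─ "G22140GZ"
          ─ glycan:is_from_source ─ source ─ glycan:has_taxon / has_tissue / has_cell_line
          ─ glycan:published_in ─ citation ─ glycan:has_pmid + dcterms:references
          ─ glycan:has_association ─ assoc ─ sio:SIO_000628 ─ disease ─ rdfs:label + skos:notation
```

Each source database gets its own RDF named graph, so one dataset holds all
descriptions side by side and queries can compare them. Positions are 1-based
UniProt residue numbers (FALDO exact positions); glycans are referenced by
GlyTouCan accession (`G#####XX`); abundance ratios are fractions in [0, 1].

## Worked example

The package ships the three-database integration example for haptoglobin
(UniProt P00738) as a fixture, with GlyConnect, UniCarbKB and GlycoNAVI each
occupying one named graph:

```r
library(glycocoo)

hp <- fixture_haptoglobin()
hp
#> <glyco_dataset> 194 triples, 3 named graph(s)
#>   <http://glycoinfo.org/glycocoo/glyconavi>: 63 triples
#>   <http://glycoinfo.org/glycocoo/glyconnect>: 68 triples
#>   <http://glycoinfo.org/glycocoo/unicarbkb>: 63 triples

sites <- run_sites(hp, "P00738")      # published site query, offline
overlap_summary(sites, "position")
#> <overlap_summary> 5 value(s) across 3 graph(s)
#>   common to all:  184, 207, 211
#>   shared by some: 241
#>   unique to one:  187

overlap_summary(run_glycans(hp, "P00738"), "glytoucan_id")
#> <overlap_summary> 10 value(s) across 3 graph(s)
#>   common to all:  G22140GZ, G36131WL, G42358LZ, G62165AG
#>   shared by some:
#>   unique to one:  G10001AA, G10002AB, G20001BA, G20002BB, G30001CA, G30002CB
```

Reading the output: all three databases agree on sites 184, 207 and 211;
site 241 is reported by two of them and 187 by UniCarbKB alone. Four glycan
accessions are shared across the graphs; the six unshared ones here are
synthetic placeholders standing in for each database's private annotations.
`run_diseases()`, `run_publications()` and `run_sources()` expose the disease,
citation and source queries the same way, and `validate_dataset(hp)` confirms
the dataset satisfies every structural shape the queries assume.

The published queries target a live endpoint for GlycoNAVI through a SPARQL
`SERVICE` clause. `rewrite_service()` strips that indirection so the verbatim
texts evaluate against local graph copies:

```r
q <- canned_query("sites")                                  # as published
sparql_select(hp, rewrite_service(q, "https://sparql.glyconavi.org/sparql"))
```

### Command line

A thin CLI wraps the same functions (`build`, `validate`, `query`, `fixture`,
`synth`); after installation:

```sh
GLYCOCOO=$(Rscript -e 'cat(system.file("exec", "glycocoo", package = "glycocoo"))')
Rscript "$GLYCOCOO" fixture haptoglobin --out hp.trig
Rscript "$GLYCOCOO" query sites --dataset hp.trig --uniprot P00738
Rscript "$GLYCOCOO" validate hp.trig
```

Exit codes: 0 success, 1 validation failure, 2 usage/parse error. Data goes
to standard output, diagnostics to standard error.

## Scope

Turtle/TriG/N-Quads only (no RDF/XML or JSON-LD); the SPARQL evaluator covers
the SELECT fragment the integration queries use (BGPs, GRAPH, OPTIONAL,
UNION, VALUES, DISTINCT, `str()`, ORDER BY) and rejects the rest with a clear
error; no OWL reasoning; no live endpoint hosting. See the methods vignette
(`vignettes/glycocoo-toolkit.Rmd`) for design decisions and limitations.
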