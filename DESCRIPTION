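Package: glycocoo
Title: Build, Validate, Serialize and Query Glycoconjugate RDF Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for the GlycoCoO glycoconjugate ontology: typed builders
    that emit schema-conformant RDF descriptions of glycoproteins and
    glycolipids (glycosylation sites, GlyTouCan-referenced glycans, abundance
    ratios, biological sources, disease associations and citations) into
    named-graph datasets; a canonical, diff-stable reader/writer for Turtle,
    TriG and N-Quads; structural shape validation against the query patterns
    the ontology's canned SPARQL queries assume; a SPARQL SELECT evaluator
    with local SERVICE-clause rewriting so federated queries run offline;
    cross-database overlap summaries; reference fixtures for the haptoglobin
    (UniProt P00738) three-database integration example; and a seeded
    synthetic-data generator with ground-truth tables for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
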