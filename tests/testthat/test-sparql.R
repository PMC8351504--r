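# micro-dataset for hand-checkable evaluations
micro_dataset <- function() {
  ds <- new_dataset()
  g1 <- iri("http://g/1"); g2 <- iri("http://g/2")
  add_quads(ds, g1, iri("http://a/x"), iri("http://p/knows"), iri("http://a/y"))
  add_quads(ds, g1, iri("http://a/y"), iri("http://p/name"), lit_string("why"))
  add_quads(ds, g1, iri("http://a/x"), iri("http://p/age"), lit_integer(30L))
  add_quads(ds, g2, iri("http://a/x"), iri("http://p/knows"), iri("http://a/z"))
  add_quads(ds, g2, iri("http://a/z"), iri("http://p/age"), lit_integer(7L))
  ds
}

test_that("basic graph patterns join across triples", {
  ds <- micro_dataset()
  res <- sparql_select(ds, "
    select ?who ?name where {
      graph <http://g/1> {
        ?x <http://p/knows> ?who .
        ?who <http://p/name> ?name .
      }
    }")
  expect_equal(res$who, "http://a/y")
  expect_equal(res$name, "why")
})

test_that("OPTIONAL keeps rows with unbound variables", {
  ds <- micro_dataset()
  res <- sparql_select(ds, "
    select ?g ?friend ?name where {
      graph ?g {
        ?x <http://p/knows> ?friend .
        optional { ?friend <http://p/name> ?name . }
      }
    } order by ?g")
  expect_equal(res$friend, c("http://a/y", "http://a/z"))
  expect_equal(res$name, c("why", NA_character_))
})

test_that("UNION, VALUES and DISTINCT behave as in the published queries", {
  ds <- micro_dataset()
  res <- sparql_select(ds, "
    select distinct ?g ?x where {
      { graph ?g { VALUES ?g { <http://g/1> } ?x <http://p/knows> ?y . } }
      UNION
      { graph ?g { VALUES ?g { <http://g/1> <http://g/2> } ?x <http://p/knows> ?y . } }
    } order by ?g")
  # duplicates from overlapping branches collapse under DISTINCT
  expect_equal(res$g, c("http://g/1", "http://g/2"))
  expect_equal(res$x, c("http://a/x", "http://a/x"))
})

test_that("str() projection and numeric ORDER BY follow SPARQL semantics", {
  ds <- micro_dataset()
  res <- sparql_select(ds, "
    select ?g (str(?a) AS ?age) where {
      graph ?g { ?x <http://p/age> ?a . }
    } order by ?a")
  expect_equal(res$age, c("7", "30"))  # numeric, not lexicographic
})

test_that("unsupported constructs and unknown formats are rejected", {
  ds <- micro_dataset()
  expect_error(sparql_select(ds, "select ?x where { FILTER(bound(?x)) }"),
               "unsupported")
  expect_error(sparql_select(ds, "select where { ?s ?p ?o }"), "syntax error")
})

test_that("queries are insensitive to triple insertion order and format", {
  hp <- fixture_haptoglobin()
  q <- dataset_quads(hp)
  shuffled <- new_dataset()
  set.seed(1)
  ord <- sample(nrow(q))
  add_quads(shuffled, q$graph[ord], q$subject[ord], q$predicate[ord],
            q$object[ord])
  expect_same_rows(run_sites(shuffled, "P00738"), run_sites(hp, "P00738"))
  via_nq <- parse_dataset(write_dataset(hp, "nquads"), "nquads")
  expect_same_rows(run_glycans(via_nq, "P00738"), run_glycans(hp, "P00738"))
})

test_that("rewrite_service substitutes mapped endpoints and keeps semantics", {
  q <- canned_query("sites")
  expect_match(q, "SERVICE <https://sparql.glyconavi.org/sparql>", fixed = TRUE)
  rw <- rewrite_service(q, "https://sparql.glyconavi.org/sparql")
  expect_false(grepl("SERVICE", rw))
  # rewriting preserves the GlycoNAVI graph pattern itself
  expect_match(rw, "glycocoo/glyconavi", fixed = TRUE)
  hp <- fixture_haptoglobin()
  res <- sparql_select(hp, rw)
  expect_true("http://glycoinfo.org/glycocoo/glyconavi" %in% res$g)
})

test_that("a query without SERVICE passes through rewrite unchanged", {
  q <- "select ?s where { ?s ?p ?o . }"
  expect_identical(rewrite_service(q, character(0)), q)
})

test_that("an unmapped SERVICE endpoint is an error naming the IRI", {
  q <- paste(
    "select ?s where {",
    "  SERVICE <http://known.example/sparql> { ?s ?p ?o . }",
    "  SERVICE <http://unknown.example/sparql> { ?s ?q ?v . }",
    "}")
  expect_error(rewrite_service(q, "http://known.example/sparql"),
               "http://unknown.example/sparql")
  # passthrough mode leaves the unmapped clause for live federation
  rw <- rewrite_service(q, "http://known.example/sparql", passthrough = TRUE)
  expect_false(grepl("SERVICE <http://known.example/sparql>", rw, fixed = TRUE))
  expect_match(rw, "SERVICE <http://unknown.example/sparql>", fixed = TRUE)
  # evaluating an un-rewritten SERVICE clause offline is an error
  expect_error(sparql_select(new_dataset(), q), "SERVICE")
})

test_that("local SERVICE rewriting equals evaluation of the inlined query", {
  hp <- fixture_haptoglobin()
  for (name in c("sites", "glycans", "diseases", "publications", "sources")) {
    q <- canned_query(name, uniprot_id = "P00738")
    rewritten <- sparql_select(hp, rewrite_service(q, .glyconavi_endpoint))
    # independently inlined: drop the SERVICE keyword by hand
    manual <- gsub("SERVICE <https://sparql.glyconavi.org/sparql>", "", q,
                   fixed = TRUE)
    inlined <- sparql_select(hp, manual)
    expect_equal(rewritten, inlined, ignore_attr = TRUE)
  }
})
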