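test_that("builder-produced datasets validate with zero violations", {
  expect_true(validate_dataset(fixture_haptoglobin())$conforms)
  expect_true(validate_dataset(fixture_worked_example())$conforms)
  expect_true(validate_dataset(
    synth_dataset(synth_params(n_proteins = 6, seed = 5))$dataset)$conforms)
  expect_true(validate_dataset(new_dataset())$conforms)
})

test_that("a deleted UniProt identifier triple raises exactly one R2 violation", {
  ds <- fixture_worked_example()
  q <- dataset_quads(ds)
  idx <- which(q$predicate == curie("dcterms:identifier") &
                 q$object == lit_string("Q9EQH7"))
  expect_length(idx, 1L)
  remove_quads(ds, idx)
  rep <- validate_dataset(ds)
  expect_false(rep$conforms)
  expect_equal(rep$violations$rule_id, "R2")
  expect_equal(nrow(rep$violations), 1L)
})

test_that("a zero position raises exactly one R3 violation", {
  ds <- fixture_worked_example()
  q <- dataset_quads(ds)
  idx <- which(q$predicate == curie("faldo:position"))
  expect_length(idx, 1L)
  loc <- q$subject[idx]
  g <- q$graph[idx]
  remove_quads(ds, idx)
  add_quads(ds, g, loc, curie("faldo:position"), lit_integer(0L))
  rep <- validate_dataset(ds)
  expect_false(rep$conforms)
  expect_equal(rep$violations$rule_id, "R3")
  expect_equal(nrow(rep$violations), 1L)
})

test_that("deleting any query-critical triple breaks conformance", {
  ds0 <- fixture_haptoglobin()
  q <- dataset_quads(ds0)
  critical <- curie(c("gco:has_protein_part", "gco:has_protein",
                      "rdfs:seeAlso", "dcterms:identifier",
                      "faldo:location", "faldo:position",
                      "foaf:primaryTopicOf", "rdfs:label", "skos:notation",
                      "glycan:has_pmid", "dcterms:references"))
  idx <- which(q$predicate %in% critical)
  expect_gt(length(idx), 50L)
  for (i in idx) {
    ds <- fixture_haptoglobin()  # fresh copy, same deterministic quad order
    remove_quads(ds, i)
    rep <- validate_dataset(ds)
    expect_false(rep$conforms,
                 info = paste("deletion left dataset conformant:",
                              q$subject[i], q$predicate[i], q$object[i]))
  }
})

test_that("the report is independent of triple insertion order", {
  make <- function(reversed) {
    ds <- fixture_haptoglobin()
    q <- dataset_quads(ds)
    idx <- which(q$predicate == curie("gco:has_protein"))[1]
    remove_quads(ds, idx)
    q2 <- dataset_quads(ds)
    ord <- if (reversed) rev(seq_len(nrow(q2))) else seq_len(nrow(q2))
    out <- new_dataset()
    add_quads(out, q2$graph[ord], q2$subject[ord], q2$predicate[ord],
              q2$object[ord])
    validate_dataset(out)
  }
  a <- make(FALSE)
  b <- make(TRUE)
  expect_false(a$conforms)
  expect_equal(a$violations, b$violations)
})

test_that("a saccharide part without site mapping is not an error", {
  ds <- new_dataset()
  build_conjugate(ds, hp_graphs["glyconavi"],
                  glyco_record("P43121", glycans = "G54321ZZ"))
  expect_true(validate_dataset(ds)$conforms)
})
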