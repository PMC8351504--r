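test_that("a new dataset is empty and independent of prior datasets", {
  a <- new_dataset()
  expect_equal(triple_count(a), 0L)
  expect_equal(graph_names(a), character(0))
  add_quads(a, iri("http://g/1"), iri("http://s"), iri("http://p"),
            lit_string("x"))
  b <- new_dataset()
  expect_equal(triple_count(b), 0L)
  expect_equal(triple_count(a), 1L)
})

test_that("triple sets deduplicate and are order-independent", {
  a <- new_dataset()
  b <- new_dataset()
  quads <- list(
    c("http://g/1", "http://s1", "http://p", "v1"),
    c("http://g/1", "http://s2", "http://p", "v2"),
    c("http://g/2", "http://s1", "http://p", "v3"))
  for (q in quads) {
    add_quads(a, iri(q[1]), iri(q[2]), iri(q[3]), lit_string(q[4]))
  }
  for (q in rev(quads)) {
    add_quads(b, iri(q[1]), iri(q[2]), iri(q[3]), lit_string(q[4]))
    add_quads(b, iri(q[1]), iri(q[2]), iri(q[3]), lit_string(q[4]))  # dup
  }
  expect_equal(triple_count(b), 3L)
  expect_true(datasets_equal(a, b))
  expect_equal(graph_names(a), c("http://g/1", "http://g/2"))
})

test_that("merge_datasets unions graphs and drops duplicates", {
  a <- new_dataset()
  add_quads(a, iri("http://g/1"), iri("http://s"), iri("http://p"),
            lit_string("x"))
  b <- new_dataset()
  add_quads(b, iri("http://g/1"), iri("http://s"), iri("http://p"),
            lit_string("x"))
  add_quads(b, iri("http://g/2"), iri("http://s"), iri("http://p"),
            lit_string("y"))
  m <- merge_datasets(a, b)
  expect_equal(triple_count(m), 2L)
  expect_equal(graph_names(m), c("http://g/1", "http://g/2"))
  # inputs untouched
  expect_equal(triple_count(a), 1L)
})
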