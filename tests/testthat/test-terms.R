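test_that("IRI terms require an absolute IRI", {
  expect_equal(iri("http://example.org/x"), "<http://example.org/x>")
  expect_error(iri("no-scheme-here/x"), "absolute IRI")
  expect_error(iri(""), "absolute IRI")
  expect_error(iri("http://bad iri/with space"), "absolute IRI")
})

test_that("literal encoding survives escaping round-trips", {
  tricky <- c("plain", "with \"quotes\"", "tab\tand\nnewline",
              "back\\slash", "unicode éß")
  for (x in tricky) {
    expect_identical(term_str(lit_string(x)), x)
  }
  expect_identical(term_str(lit_integer(184L)), "184")
  expect_identical(term_numeric(lit_integer(184L)), 184)
  expect_identical(term_numeric(lit_decimal(0.25)), 0.25)
  expect_true(is.na(term_numeric(lit_string("184"))))
})

test_that("curie expansion uses the declared namespaces", {
  expect_equal(curie("gco:has_protein"),
               "<http://purl.jp/bio/12/glyco/conjugate#has_protein>")
  expect_equal(curie("faldo:position"),
               "<http://biohackathon.org/resource/faldo#position>")
  expect_error(curie("nope:thing"), "undeclared prefix")
})

test_that("vocabulary table matches the published query prefixes", {
  v <- vocabulary()
  ns <- setNames(v$namespace, v$prefix)
  expect_equal(unname(ns["gco"]), "http://purl.jp/bio/12/glyco/conjugate#")
  expect_equal(unname(ns["glycan"]), "http://purl.jp/bio/12/glyco/glycan#")
  expect_equal(unname(ns["faldo"]), "http://biohackathon.org/resource/faldo#")
  expect_equal(unname(ns["sio"]), "http://semanticscience.org/resource/")
  expect_equal(unname(ns["skos"]), "http://www.w3.org/2008/05/skos#")
  expect_equal(unname(ns["up"]), "http://purl.uniprot.org/core/")
  expect_true(all(c("dcterms", "foaf", "rdfs", "gcx") %in% v$prefix))
})
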