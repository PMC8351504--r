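test_that("parameter validation rejects bad ranges and sizes", {
  expect_error(synth_params(n_proteins = -1), "non-negative")
  expect_error(synth_params(sites_per_protein = c(5, 1)), "lo <= hi")
  expect_error(synth_params(glycans_per_site = c(-2, 1)), "lo <= hi")
  expect_error(synth_params(graph_names = character(0)), "at least one")
  expect_error(synth_dataset(list(n_proteins = 2)), "synth_params")
})

test_that("zero proteins gives an empty dataset and empty ground truth", {
  out <- synth_dataset(synth_params(n_proteins = 0, seed = 1))
  expect_equal(triple_count(out$dataset), 0L)
  expect_true(all(vapply(out$truth, nrow, integer(1)) == 0L))
})

test_that("the same seed reproduces byte-identical serializations", {
  a <- synth_dataset(synth_params(n_proteins = 6, seed = 123))
  b <- synth_dataset(synth_params(n_proteins = 6, seed = 123))
  expect_identical(write_dataset(a$dataset, "trig"),
                   write_dataset(b$dataset, "trig"))
  expect_identical(a$truth, b$truth)
  c <- synth_dataset(synth_params(n_proteins = 6, seed = 124))
  expect_false(identical(write_dataset(a$dataset, "trig"),
                         write_dataset(c$dataset, "trig")))
})

test_that("the generator restores the session RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(synth_dataset(synth_params(n_proteins = 2, seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("all five queries recover exactly the generated ground truth", {
  out <- synth_dataset(synth_params(n_proteins = 8, seed = 31))
  ds <- out$dataset
  for (u in sprintf("P%05d", 1:8)) {
    got <- run_all_queries(ds, u)
    want <- truth_for(out$truth, u)
    for (fam in names(got)) {
      expect_same_rows(got[[fam]], want[[fam]])
    }
  }
})

test_that("richness flags switch metadata families off", {
  out <- synth_dataset(synth_params(n_proteins = 4, seed = 9,
                                    diseases = FALSE, citations = FALSE,
                                    sources = FALSE, abundances = FALSE))
  expect_equal(nrow(out$truth$diseases), 0L)
  expect_equal(nrow(out$truth$publications), 0L)
  expect_equal(nrow(out$truth$sources), 0L)
  q <- dataset_quads(out$dataset)
  expect_false(any(q$predicate == curie("gcx:has_abundance_ratio")))
  expect_true(validate_dataset(out$dataset)$conforms)
})
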