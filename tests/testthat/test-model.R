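test_that("record validation rejects malformed fields by name", {
  expect_error(glyco_record("NOTANID"), "UniProt")
  expect_error(glyco_record("P00738", sites = 0L), "1-based")
  expect_error(glyco_record("P00738", sites = -3L), "1-based")
  expect_error(glyco_record("P00738", glycans = "BADID"), "GlyTouCan")
  expect_error(glyco_record("P00738", glycans = data.frame(
    glytoucan_id = "G22140GZ", abundance = 1.5)), "\\[0, 1\\]")
  expect_error(glyco_record("P00738",
                            diseases = data.frame(label = "", notation = "X")),
               "label")
  expect_error(glyco_record("P00738",
                            diseases = data.frame(label = "x", notation = "")),
               "notation")
  expect_error(glyco_record("P00738", pmids = 0L), "positive")
  # both 6- and 10-character accession forms are accepted
  expect_s3_class(glyco_record("Q9EQH7"), "glyco_record")
  expect_s3_class(glyco_record("A0A0B4J2F0"), "glyco_record")
})

test_that("building a single-site record makes the site retrievable", {
  ds <- new_dataset()
  build_conjugate(ds, "http://glycoinfo.org/glycocoo/example",
                  glyco_record("Q9EQH7", sites = 146L))
  rows <- run_sites(ds, "Q9EQH7")
  expect_equal(rows$position, 146L)
  expect_equal(rows$uniprot_id, "Q9EQH7")
})

test_that("a record with no sites and no glycans yields empty query results", {
  ds <- new_dataset()
  build_conjugate(ds, "http://glycoinfo.org/glycocoo/example",
                  glyco_record("P00738"))
  expect_equal(nrow(run_sites(ds, "P00738")), 0L)
  expect_equal(nrow(run_glycans(ds, "P00738")), 0L)
  expect_true(validate_dataset(ds)$conforms)
})

test_that("emitted triple counts match an independent schema expansion", {
  # hand expansion of the builder pattern:
  #   conjugate core: type, has_protein_part, part type, has_protein,
  #                   seeAlso, identifier                      -> 6
  #   per site: glycosylated_at, location, location type, position -> 4
  #   per glycan: has_saccharide_part, has_glycan, primaryTopicOf,
  #               identifier (+1 if abundance given)           -> 4 (+1)
  #   source: is_from_source, has_taxon (+organism +tissue +cell line)
  #   per pmid: published_in, has_pmid, references             -> 3
  #   per disease: has_association, SIO_000628, label, notation -> 4
  rec <- full_record()
  expected <- 6 + 2 * 4 + (3 * 4 + 2) + (2 + 3) + 2 * 3 + 2 * 4
  ds <- new_dataset()
  build_conjugate(ds, hp_graphs["glyconnect"], rec)
  expect_equal(triple_count(ds), expected)
  # query-side counts: 2 positions, 3 accessions
  expect_equal(nrow(run_sites(ds, "P12345")), 2L)
  expect_equal(nrow(run_glycans(ds, "P12345")), 3L)
})

test_that("building the same record twice is idempotent with stable IRIs", {
  ds1 <- new_dataset()
  ds2 <- new_dataset()
  build_conjugate(ds1, hp_graphs["unicarbkb"], full_record())
  n <- triple_count(ds1)
  build_conjugate(ds1, hp_graphs["unicarbkb"], full_record())
  expect_equal(triple_count(ds1), n)
  build_conjugate(ds2, hp_graphs["unicarbkb"], full_record())
  expect_true(datasets_equal(ds1, ds2))
  expect_identical(write_dataset(ds1, "trig"), write_dataset(ds2, "trig"))
})

test_that("add_glycosylation_site enforces 1-based positions and reuses regions", {
  ds <- new_dataset()
  conj <- build_conjugate(ds, hp_graphs["glyconnect"], glyco_record("Q9EQH7"))
  reg <- add_glycosylation_site(conj$protein_part, 146L)
  expect_equal(reg$position, 146L)
  expect_error(add_glycosylation_site(conj$protein_part, 0L), "1-based")
  n <- triple_count(ds)
  reg2 <- add_glycosylation_site(conj$protein_part, 146L)
  expect_equal(triple_count(ds), n)
  expect_identical(reg2$node, reg$node)
})

test_that("add_saccharide stores and returns abundance ratios", {
  ds <- new_dataset()
  conj <- build_conjugate(ds, hp_graphs["glyconavi"], glyco_record("P00738"))
  expect_error(add_saccharide(conj, "BADID"), "GlyTouCan")
  expect_error(add_saccharide(conj, "G36131WL", abundance = 1.2), "\\[0, 1\\]")
  part <- add_saccharide(conj, "G36131WL", abundance = 0.25)
  q <- dataset_quads(ds)
  ab <- q$object[q$subject == part$node &
                   q$predicate == curie("gcx:has_abundance_ratio")]
  expect_equal(term_numeric(ab), 0.25)
  expect_equal(run_glycans(ds, "P00738")$glytoucan_id, "G36131WL")
})

test_that("add_metadata with empty citations yields no publication rows", {
  ds <- new_dataset()
  conj <- build_conjugate(ds, hp_graphs["glyconnect"], glyco_record("P00738"))
  add_metadata(conj, source = list(taxon = "http://purl.uniprot.org/taxonomy/9606"),
               citations = integer(0))
  expect_equal(nrow(run_publications(ds, "P00738")), 0L)
  src <- run_sources(ds, "P00738")
  expect_equal(nrow(src), 1L)
  expect_true(is.na(src$organism) && is.na(src$tissue) && is.na(src$cell_line))
})

test_that("a lipid-only conjugate satisfies the part requirement", {
  ds <- new_dataset()
  conj <- build_conjugate(ds, hp_graphs["glyconavi"], glyco_record("P99999"))
  add_lipid_part(conj, "lipid-1")
  expect_true(validate_dataset(ds)$conforms)
})

test_that("every emitted predicate belongs to the declared vocabulary", {
  ds <- synth_dataset(synth_params(n_proteins = 5, seed = 3))$dataset
  preds <- unique(term_str(dataset_quads(ds)$predicate))
  ns <- vocabulary()$namespace
  in_vocab <- vapply(preds, function(p) {
    any(startsWith(p, ns))
  }, logical(1))
  expect_true(all(in_vocab))
})
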