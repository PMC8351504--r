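# shared helpers for the test suite

hp_graphs <- c(
  glyconnect = "http://glycoinfo.org/glycocoo/glyconnect",
  unicarbkb = "http://glycoinfo.org/glycocoo/unicarbkb",
  glyconavi = "http://glycoinfo.org/glycocoo/glyconavi")

# a small but fully populated record for builder tests
full_record <- function(uniprot = "P12345") {
  glyco_record(
    uniprot,
    sites = c(12L, 97L),
    glycans = data.frame(glytoucan_id = c("G11111AA", "G22222BB", "G33333CC"),
                         abundance = c(0.5, NA, 0.1),
                         stringsAsFactors = FALSE),
    taxon = "http://purl.uniprot.org/taxonomy/9606",
    organism = "Homo sapiens",
    tissue = "http://glycoinfo.org/glycocoo/synthetic/tissue/tissue-9",
    cell_line = "http://glycoinfo.org/glycocoo/synthetic/cell-line/cell-line-9",
    diseases = data.frame(label = c("synthetic disease a", "synthetic disease b"),
                          notation = c("SYN:T0001", "SYN:T0002"),
                          stringsAsFactors = FALSE),
    pmids = c(11111111L, 22222222L))
}

# row-set comparison ignoring row names
expect_same_rows <- function(got, want) {
  rownames(got) <- NULL
  rownames(want) <- NULL
  expect_equal(got, want, ignore_attr = TRUE)
}

# run all five typed queries for one accession
run_all_queries <- function(ds, u) {
  list(sites = run_sites(ds, u),
       glycans = run_glycans(ds, u),
       diseases = run_diseases(ds, u),
       publications = run_publications(ds, u),
       sources = run_sources(ds, u))
}

# slice a ground-truth list down to one accession
truth_for <- function(truth, u) {
  lapply(truth, function(df) {
    out <- df[df$uniprot_id == u, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
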