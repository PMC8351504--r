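test_that("haptoglobin site lists match the per-database annotations", {
  hp <- fixture_haptoglobin()
  s <- run_sites(hp, "P00738")
  by_graph <- split(s$position, s$graph)
  expect_equal(sort(by_graph[[hp_graphs[["glyconnect"]]]]),
               c(184L, 207L, 211L, 241L))
  expect_equal(sort(by_graph[[hp_graphs[["glyconavi"]]]]),
               c(184L, 207L, 211L))
  expect_equal(sort(by_graph[[hp_graphs[["unicarbkb"]]]]),
               c(184L, 187L, 207L, 211L, 241L))
  expect_equal(nrow(s), 12L)  # 4 + 3 + 5
})

test_that("the four shared glycan accessions are bound in multiple graphs", {
  hp <- fixture_haptoglobin()
  g <- run_glycans(hp, "P00738")
  ov <- overlap_summary(g, "glytoucan_id")
  multi <- c(ov$common_to_all, ov$shared_by_some)
  expect_setequal(multi, c("G22140GZ", "G36131WL", "G42358LZ", "G62165AG"))
  expect_length(ov$unique_to_one, 6L)  # two synthetic accessions per graph
})

test_that("disease sharing matches the cross-database pattern", {
  hp <- fixture_haptoglobin()
  d <- run_diseases(hp, "P00738")
  graphs_of <- function(lab) sort(unique(d$graph[d$disease_label == lab]))
  expect_equal(graphs_of("esophageal cancer"),
               sort(unname(hp_graphs[c("glyconnect", "unicarbkb")])))
  expect_equal(graphs_of("hepatocellular carcinoma"),
               sort(unname(hp_graphs[c("glyconavi", "glyconnect")])))
  ov <- overlap_summary(d, "disease_label")
  expect_length(ov$common_to_all, 0L)
  expect_length(ov$unique_to_one, 2L)  # one extra cancer each for two graphs
})

test_that("citations overlap only between UniCarbKB and GlyConnect", {
  hp <- fixture_haptoglobin()
  p <- run_publications(hp, "P00738")
  ov <- overlap_summary(p, "pmid")
  expect_length(ov$common_to_all, 0L)
  shared_graphs <- unique(unlist(ov$membership[ov$shared_by_some]))
  expect_setequal(shared_graphs,
                  unname(hp_graphs[c("glyconnect", "unicarbkb")]))
})

test_that("sources bind organism everywhere, tissue/cell line where stated", {
  hp <- fixture_haptoglobin()
  s <- run_sources(hp, "P00738")
  expect_setequal(s$graph, unname(hp_graphs))
  expect_true(all(s$organism == "Homo sapiens"))
  expect_equal(s$graph[!is.na(s$cell_line)], hp_graphs[["glyconavi"]])
  expect_equal(s$graph[!is.na(s$tissue)], hp_graphs[["glyconnect"]])
})

test_that("queries against missing accessions or empty datasets return no rows", {
  expect_equal(nrow(run_sites(new_dataset(), "P00738")), 0L)
  expect_equal(nrow(run_sites(fixture_worked_example(), "P00738")), 0L)
  expect_error(run_sites(fixture_haptoglobin(), "not-an-id"), "UniProt")
})

test_that("disease rows vanish when the notation triple is absent", {
  ds <- new_dataset()
  conj <- build_conjugate(ds, hp_graphs["glyconnect"], glyco_record("P00738"))
  add_metadata(conj, diseases = data.frame(label = "esophageal cancer",
                                           notation = "SYN:D0001"))
  q <- dataset_quads(ds)
  remove_quads(ds, which(q$predicate == curie("skos:notation")))
  expect_equal(nrow(run_diseases(ds, "P00738")), 0L)
})

test_that("citation rows require both the PMID and the PubMed reference", {
  ds <- new_dataset()
  conj <- build_conjugate(ds, hp_graphs["unicarbkb"], glyco_record("P00738"))
  add_metadata(conj, citations = 12345678L)
  q <- dataset_quads(ds)
  remove_quads(ds, which(q$predicate == curie("dcterms:references")))
  expect_equal(nrow(run_publications(ds, "P00738")), 0L)
})

test_that("overlap partitions match a brute-force regrouping", {
  brute <- function(rows, key) {
    pairs <- unique(data.frame(v = as.character(rows[[key]]), g = rows$graph,
                               stringsAsFactors = FALSE))
    uni <- sort(unique(pairs$g))
    counts <- tapply(pairs$g, pairs$v, function(g) length(unique(g)))
    list(common = sort(names(counts)[counts == length(uni) & length(uni) > 1]),
         shared = sort(names(counts)[counts > 1 & counts < length(uni)]),
         unique = sort(names(counts)[counts == 1]))
  }
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:40, 1)
    rows <- data.frame(
      graph = sample(paste0("http://g/", 1:sample(1:4, 1)), n, replace = TRUE),
      val = sample(letters[1:8], n, replace = TRUE),
      stringsAsFactors = FALSE)
    ov <- overlap_summary(rows, "val")
    bf <- brute(rows, "val")
    expect_equal(ov$common_to_all, bf$common)
    expect_equal(ov$shared_by_some, bf$shared)
    expect_equal(ov$unique_to_one, bf$unique)
    # partitions disjoint and exhaustive
    all_parts <- c(ov$common_to_all, ov$shared_by_some, ov$unique_to_one)
    expect_false(any(duplicated(all_parts)))
    expect_setequal(all_parts, unique(rows$val))
  }
})

test_that("rows from a single graph are all unique-to-one", {
  rows <- data.frame(graph = "http://g/only", val = c("a", "b", "a"),
                     stringsAsFactors = FALSE)
  ov <- overlap_summary(rows, "val")
  expect_equal(ov$unique_to_one, c("a", "b"))
  expect_length(ov$common_to_all, 0L)
  expect_length(ov$shared_by_some, 0L)
})
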