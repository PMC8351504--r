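# Reference fixtures. fixture_haptoglobin() encodes, graph by graph, every
# cross-database statement of the three-database haptoglobin (P00738)
# integration example; fixture_worked_example() encodes the Q9EQH7
# single-site example. Identifiers the integration example does not state
# (disease notations, PMIDs, tissue/cell-line IRIs, the per-database
# non-shared glycan accessions, the worked example's glycan) are synthetic
# placeholders, recognisable as such from their values, chosen so that every
# stated sharing pattern holds exactly.

.g_glyconnect <- "http://glycoinfo.org/glycocoo/glyconnect"
.g_unicarbkb <- "http://glycoinfo.org/glycocoo/unicarbkb"
.g_glyconavi <- "http://glycoinfo.org/glycocoo/glyconavi"
.taxon_human <- "http://purl.uniprot.org/taxonomy/9606"
.synth_ns <- "http://glycoinfo.org/glycocoo/synthetic/"

#' Three-database haptoglobin integration fixture
#'
#' A dataset with exactly the named graphs
#' `<http://glycoinfo.org/glycocoo/glyconnect>`, `<.../unicarbkb>` and
#' `<.../glyconavi>` describing haptoglobin (UniProt P00738):
#' \itemize{
#'   \item glycosylation sites: GlyConnect 184/207/211/241, GlycoNAVI
#'     184/207/211, UniCarbKB 184/187/207/211/241;
#'   \item glycans: the four accessions reported as shared (G22140GZ,
#'     G36131WL, G42358LZ, G62165AG) in all three graphs, plus two synthetic
#'     unshared accessions per graph; GlycoNAVI saccharide parts carry
#'     abundance ratios;
#'   \item diseases: esophageal cancer in GlyConnect and UniCarbKB,
#'     hepatocellular carcinoma in GlycoNAVI and GlyConnect, one additional
#'     unshared cancer each for GlycoNAVI and GlyConnect (synthetic
#'     notations);
#'   \item source: Homo sapiens in all three graphs; a cell line only in
#'     GlycoNAVI; a tissue only in GlyConnect;
#'   \item citations: synthetic PMIDs overlapping only between UniCarbKB and
#'     GlyConnect.
#' }
#' Built entirely through the model builders, so it validates with zero
#' violations and serializes byte-identically across runs.
#'
#' @return a `glyco_dataset`.
#' @export
fixture_haptoglobin <- function() {
  ds <- new_dataset()

  build_conjugate(ds, .g_glyconnect, glyco_record(
    "P00738",
    sites = c(184L, 207L, 211L, 241L),
    glycans = c("G22140GZ", "G36131WL", "G42358LZ", "G62165AG",
                "G10001AA", "G10002AB"),
    taxon = .taxon_human, organism = "Homo sapiens",
    tissue = paste0(.synth_ns, "tissue/tissue-1"),
    diseases = data.frame(
      label = c("esophageal cancer", "hepatocellular carcinoma",
                "synthetic glyconnect-only cancer"),
      notation = c("SYN:D0001", "SYN:D0002", "SYN:D0003"),
      stringsAsFactors = FALSE),
    pmids = c(90000001L, 90000003L)))

  build_conjugate(ds, .g_unicarbkb, glyco_record(
    "P00738",
    sites = c(184L, 187L, 207L, 211L, 241L),
    glycans = c("G22140GZ", "G36131WL", "G42358LZ", "G62165AG",
                "G20001BA", "G20002BB"),
    taxon = .taxon_human, organism = "Homo sapiens",
    diseases = data.frame(label = "esophageal cancer", notation = "SYN:D0001",
                          stringsAsFactors = FALSE),
    pmids = c(90000001L, 90000002L)))

  build_conjugate(ds, .g_glyconavi, glyco_record(
    "P00738",
    sites = c(184L, 207L, 211L),
    glycans = data.frame(
      glytoucan_id = c("G22140GZ", "G36131WL", "G42358LZ", "G62165AG",
                       "G30001CA", "G30002CB"),
      abundance = c(0.30, 0.25, 0.20, 0.15, 0.05, 0.05),
      stringsAsFactors = FALSE),
    taxon = .taxon_human, organism = "Homo sapiens",
    cell_line = paste0(.synth_ns, "cell-line/cell-line-1"),
    diseases = data.frame(
      label = c("hepatocellular carcinoma", "synthetic glyconavi-only cancer"),
      notation = c("SYN:D0002", "SYN:D0004"),
      stringsAsFactors = FALSE),
    pmids = 90000004L))

  ds
}

#' Single-site worked example fixture (Q9EQH7)
#'
#' One named graph (`<http://glycoinfo.org/glycocoo/example>`) holding the
#' schema chain for UniProt Q9EQH7 with its glycosylation site at position
#' 146 (an asparagine) and one attached glycan (synthetic accession, as the
#' example names none).
#'
#' @return a `glyco_dataset`.
#' @export
fixture_worked_example <- function() {
  ds <- new_dataset()
  build_conjugate(ds, "http://glycoinfo.org/glycocoo/example", glyco_record(
    "Q9EQH7",
    sites = 146L,
    glycans = "G00001SY",
    taxon = "http://purl.uniprot.org/taxonomy/10116"))
  ds
}
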