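# Input-side representation of one glycoconjugate observation set: a protein
# accession with its glycosylation sites, attached glycans (with optional
# abundance ratios), biological source, disease associations and citations.

.uniprot_regex <-
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
.glytoucan_regex <- "^G[0-9]{5}[A-Z]{2}$"

is_uniprot_accession <- function(x) grepl(.uniprot_regex, x)
is_glytoucan_accession <- function(x) grepl(.glytoucan_regex, x)

#' Construct a glycoconjugate record
#'
#' A flat record of everything known about one glycoprotein from one source
#' database: UniProt accession, 1-based glycosylation site positions, attached
#' glycans referenced by GlyTouCan accession (optionally with an abundance
#' ratio in \[0, 1\]), NCBI-taxonomy source with optional tissue and cell
#' line, disease associations as (label, notation) pairs, and PubMed IDs.
#' Sites and glycans are independent: records with glycans but no site
#' mapping (or the reverse) are valid, matching partially site-resolved
#' glycoproteomics data.
#'
#' @param uniprot_id UniProt accession (6- or 10-character form).
#' @param sites integer vector of 1-based residue positions.
#' @param glycans character vector of GlyTouCan accessions, or a data.frame
#'   with columns `glytoucan_id` and `abundance` (`NA` allowed).
#' @param taxon optional taxon IRI string (e.g. a purl.uniprot.org/taxonomy
#'   IRI).
#' @param organism optional scientific name literal for the taxon.
#' @param tissue,cell_line optional ontology IRI strings.
#' @param diseases data.frame with columns `label` and `notation`, or a list
#'   of length-2 character vectors.
#' @param pmids integer vector of positive PubMed IDs.
#' @return an object of class `glyco_record`.
#' @export
#' @examples
#' glyco_record("Q9EQH7", sites = 146, glycans = "G00001SY")
glyco_record <- function(uniprot_id, sites = integer(0),
                         glycans = character(0),
                         taxon = NULL, organism = NULL,
                         tissue = NULL, cell_line = NULL,
                         diseases = NULL, pmids = integer(0)) {
  if (length(uniprot_id) != 1L || !is_uniprot_accession(uniprot_id)) {
    stop("uniprot_id: not a valid UniProt accession: ",
         paste(uniprot_id, collapse = ", "), call. = FALSE)
  }
  sites <- as.integer(sites)
  if (anyNA(sites) || any(sites < 1L)) {
    stop("sites: positions are 1-based and must be >= 1", call. = FALSE)
  }
  if (is.character(glycans)) {
    glycans <- data.frame(glytoucan_id = glycans,
                          abundance = rep(NA_real_, length(glycans)),
                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(glycans) ||
      !all(c("glytoucan_id", "abundance") %in% names(glycans))) {
    stop("glycans: need accessions or a data.frame(glytoucan_id, abundance)",
         call. = FALSE)
  }
  bad <- !is_glytoucan_accession(glycans$glytoucan_id)
  if (any(bad)) {
    stop("glycans: not a GlyTouCan accession (G#####XX): ",
         paste(glycans$glytoucan_id[bad], collapse = ", "), call. = FALSE)
  }
  ab <- glycans$abundance
  if (any(!is.na(ab) & (ab < 0 | ab > 1))) {
    stop("glycans: abundance ratios must lie in [0, 1]", call. = FALSE)
  }
  if (is.list(diseases) && !is.data.frame(diseases)) {
    diseases <- data.frame(
      label = vapply(diseases, `[`, character(1), 1L),
      notation = vapply(diseases, `[`, character(1), 2L),
      stringsAsFactors = FALSE)
  }
  if (is.null(diseases)) {
    diseases <- data.frame(label = character(0), notation = character(0),
                           stringsAsFactors = FALSE)
  }
  if (!all(c("label", "notation") %in% names(diseases))) {
    stop("diseases: need columns label and notation", call. = FALSE)
  }
  if (any(is.na(diseases$label) | !nzchar(diseases$label))) {
    stop("diseases: empty label", call. = FALSE)
  }
  if (any(is.na(diseases$notation) | !nzchar(diseases$notation))) {
    stop("diseases: empty notation", call. = FALSE)
  }
  pmids <- as.integer(pmids)
  if (anyNA(pmids) || any(pmids < 1L)) {
    stop("pmids: PubMed IDs must be positive integers", call. = FALSE)
  }
  structure(list(
    uniprot_id = uniprot_id,
    sites = unique(sites),
    glycans = unique(glycans),
    taxon = taxon, organism = organism,
    tissue = tissue, cell_line = cell_line,
    diseases = unique(diseases),
    pmids = unique(pmids)
  ), class = "glyco_record")
}

#' @export
print.glyco_record <- function(x, ...) {
  cat(sprintf("<glyco_record> %s: %d site(s), %d glycan(s), %d disease(s), %d PMID(s)\n",
              x$uniprot_id, length(x$sites), nrow(x$glycans),
              nrow(x$diseases), length(x$pmids)))
  invisible(x)
}
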