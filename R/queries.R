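# The five published integration queries, stored verbatim (including their
# quirks: duplicated dcterms prefix lines, reliance on an undeclared rdfs
# prefix, 'str (?pmid)' spacing, and the 2008 skos namespace), plus typed
# wrappers that run them offline via SERVICE rewriting.

.glyconavi_endpoint <- "https://sparql.glyconavi.org/sparql"

.q_sites <- '
prefix gco:<http://purl.jp/bio/12/glyco/conjugate#>
prefix dcterms:<http://purl.org/dc/terms/>
prefix faldo:<http://biohackathon.org/resource/faldo#>
prefix dcterms:<http://purl.org/dc/terms/>
select distinct ?g ?uniprot_id (str(?position) AS ?site)
where
{
  {
    graph ?g {
      VALUES ?g { <http://glycoinfo.org/glycocoo/glyconnect> <http://glycoinfo.org/glycocoo/unicarbkb>}
      # GlyConnect and UniCarbKB
      ?ref_conjugate gco:has_protein_part ?ref_protein.
      ?ref_protein gco:glycosylated_at ?region .
      ?region faldo:location ?location .
      ?location faldo:position ?position .
      ?ref_protein gco:has_protein ?protein .
      ?protein rdfs:seeAlso ?uniprot .
      ?uniprot dcterms:identifier ?uniprot_id .
    }
  }
  UNION
  {
    # GlycoNAVI
    SERVICE <https://sparql.glyconavi.org/sparql> {
      graph ?g {
        VALUES ?g { <http://glycoinfo.org/glycocoo/glyconavi> }
        ?ref_conjugate gco:has_protein_part ?ref_protein .
        ?ref_protein gco:glycosylated_at ?region .
        ?region faldo:location ?location .
        ?location faldo:position ?position .
        ?ref_protein gco:has_protein ?protein .
        ?protein rdfs:seeAlso ?uniprot .
        ?uniprot dcterms:identifier ?uniprot_id .
      }
    }
  }
}
order by ?g ?position
'

.q_glycans <- '
# Glycan Part
prefix glycan:<http://purl.jp/bio/12/glyco/glycan#>
prefix gco:<http://purl.jp/bio/12/glyco/conjugate#>
prefix dcterms:<http://purl.org/dc/terms/>
prefix faldo:<http://biohackathon.org/resource/faldo#>
prefix sio:<http://semanticscience.org/resource/>
prefix foaf:<http://xmlns.com/foaf/0.1/>
select distinct ?g ?uniprot_id ?glytoucan_id
where
{
  {
    graph ?g{
      VALUES ?g { <http://glycoinfo.org/glycocoo/glyconnect> <http://glycoinfo.org/glycocoo/unicarbkb>}
      # GlyConnect & UniCarbKB
      ?glycoconjugate_ref gco:has_protein_part ?protein_part.
      ?protein_part gco:has_protein ?protein.
      ?protein rdfs:seeAlso ?uniprot.
      ?uniprot dcterms:identifier ?uniprot_id.
      ?glycoconjugate_ref gco:has_saccharide_part ?ref_sac.
      ?ref_sac glycan:has_glycan ?saccharide.
      ?saccharide foaf:primaryTopicOf ?glytoucan.
      ?glytoucan dcterms:identifier ?glytoucan_id.
    }
  }
  UNION
  {
    # GlycoNAVI
    SERVICE <https://sparql.glyconavi.org/sparql> {
      graph ?g {
        VALUES ?g{<http://glycoinfo.org/glycocoo/glyconavi>}
        ?glycoconjugate_ref gco:has_protein_part ?protein_part.
        ?protein_part gco:has_protein ?protein.
        ?protein rdfs:seeAlso ?uniprot.
        ?uniprot dcterms:identifier ?uniprot_id.
        ?glycoconjugate_ref gco:has_saccharide_part ?ref_sac.
        ?ref_sac glycan:has_glycan ?saccharide.
        ?saccharide foaf:primaryTopicOf ?glytoucan.
        ?glytoucan dcterms:identifier ?glytoucan_id.
      }
    }
  }
}
order by ?g ?uniprot_id ?glytoucan_id
'

.q_diseases <- '
# Disease Association part
PREFIX glycan:<http://purl.jp/bio/12/glyco/glycan#>
PREFIX gco:<http://purl.jp/bio/12/glyco/conjugate#>
PREFIX skos:<http://www.w3.org/2008/05/skos#>
PREFIX dcterms:<http://purl.org/dc/terms/>
PREFIX faldo:<http://biohackathon.org/resource/faldo#>
PREFIX sio:<http://semanticscience.org/resource/>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
SELECT DISTINCT ?g ?disease_label ?notation ?uniprot_id
WHERE
{
  {
    graph ?g {
      VALUES ?g {<http://glycoinfo.org/glycocoo/glyconnect> <http://glycoinfo.org/glycocoo/unicarbkb>}
      # GlyConnect & UniCarbKB
      ?glycoconjugate_ref glycan:has_association ?association;
        gco:has_protein_part ?protein_part.
      ?association sio:SIO_000628 ?disease.
      ?disease rdfs:label ?disease_label.
      ?disease skos:notation ?notation.
      ?protein_part gco:has_protein ?protein .
      ?protein rdfs:seeAlso ?uniprot.
      ?uniprot dcterms:identifier ?uniprot_id.
      VALUES ?uniprot_id {"P00738"}
    }
  }
  UNION
  {
    # GlycoNAVI
    SERVICE <https://sparql.glyconavi.org/sparql> {
      graph ?g {
        VALUES ?g {<http://glycoinfo.org/glycocoo/glyconavi>}
        ?glycoconjugate_ref glycan:has_association ?association;
          gco:has_protein_part ?protein_part.
        ?association sio:SIO_000628 ?disease.
        ?disease rdfs:label ?disease_label.
        ?disease skos:notation ?notation.
        ?protein_part gco:has_protein ?protein.
        ?protein rdfs:seeAlso ?uniprot.
        ?uniprot dcterms:identifier ?uniprot_id.
        VALUES ?uniprot_id {"P00738"}
      }
    }
  }
}
ORDER BY ?g
'

.q_publications <- '
prefix glycan:<http://purl.jp/bio/12/glyco/glycan#>
prefix gco:<http://purl.jp/bio/12/glyco/conjugate#>
prefix dcterms:<http://purl.org/dc/terms/>
prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#>
select distinct ?g ?uniprot_id (str (?pmid) AS ?PMID)
where
{
  {
    graph ?g {
      VALUES ?g { <http://glycoinfo.org/glycocoo/glyconnect> <http://glycoinfo.org/glycocoo/unicarbkb>}
      ?glycoconjugate_ref glycan:published_in ?citation.
      ?glycoconjugate_ref gco:has_protein_part ?protein_part.
      ?protein_part gco:has_protein ?protein.
      ?protein rdfs:seeAlso ?uniprot.
      ?uniprot dcterms:identifier ?uniprot_id.
      VALUES ?uniprot_id {"P00738"}
      # glyconnect & unicarbkb
      ?citation dcterms:references ?pubmed.
      ?citation glycan:has_pmid ?pmid.
    }
  }
  UNION
  {
    # GlycoNAVI
    SERVICE <https://sparql.glyconavi.org/sparql> {
      graph ?g {
        VALUES ?g {<http://glycoinfo.org/glycocoo/glyconavi>}
        ?glycoconjugate_ref glycan:published_in ?citation.
        ?glycoconjugate_ref gco:has_protein_part ?protein_part.
        ?protein_part gco:has_protein ?protein.
        ?protein rdfs:seeAlso ?uniprot.
        ?uniprot dcterms:identifier ?uniprot_id.
        VALUES ?uniprot_id {"P00738"}
        ?citation dcterms:references ?pubmed.
        ?citation glycan:has_pmid ?pmid.
      }
    }
  }
}
order by ?g ?pmid
'

.q_sources <- '
prefix glycan:<http://purl.jp/bio/12/glyco/glycan#>
prefix gco:<http://purl.jp/bio/12/glyco/conjugate#>
prefix dcterms:<http://purl.org/dc/terms/>
prefix faldo:<http://biohackathon.org/resource/faldo#>
prefix sio:<http://semanticscience.org/resource/>
prefix dcterms:<http://purl.org/dc/terms/>
prefix up: <http://purl.uniprot.org/core/>
select distinct ?g ?uniprot_id ?tissue ?cell_line ?organism
where
{
  {
    graph ?g {
      VALUES ?g {<http://glycoinfo.org/glycocoo/glyconnect> <http://glycoinfo.org/glycocoo/unicarbkb>}
      # glyconnect & unicarbkb
      ?glycoconjugate_ref glycan:is_from_source ?source; gco:has_protein_part ?protein_part.
      optional {?source glycan:has_tissue ?tissue.}
      optional {?source glycan:has_cell_line ?cell_line.}
      ?protein_part gco:has_protein ?protein.
      ?protein rdfs:seeAlso ?uniprot.
      ?uniprot dcterms:identifier ?uniprot_id.
      VALUES ?uniprot_id {"P00738"}
      optional {
        ?source glycan:has_taxon ?taxon.
        OPTIONAL {?taxon up:scientificName ?organism.}
      }
    }
  }
  UNION
  {
    # GlycoNAVI
    SERVICE <https://sparql.glyconavi.org/sparql> {
      graph ?g {
        VALUES ?g {<http://glycoinfo.org/glycocoo/glyconavi>}
        ?glycoconjugate_ref glycan:is_from_source ?source;
          gco:has_protein_part ?protein_part.
        optional{?source glycan:has_tissue ?tissue.}
        optional{?source glycan:has_cell_line ?cell_line.}
        optional{
          ?source glycan:has_taxon ?taxon.
          optional {?taxon up:scientificName ?organism.}
        }
        ?ref_conjugate gco:has_protein_part ?ref_protein.
        ?ref_protein gco:has_protein ?protein .
        ?protein rdfs:seeAlso ?uniprot.
        ?uniprot dcterms:identifier ?uniprot_id.
        VALUES ?uniprot_id {"P00738"}
      }
    }
  }
}
order by ?g ?tissue ?cell_line ?taxon
'

#' Retrieve a canned query text by name
#'
#' The five integration queries as published: `sites`, `glycans`, `diseases`,
#' `publications`, `sources`. The `sources` query's GlycoNAVI branch binds
#' the protein chain through variables (`?ref_conjugate`/`?ref_protein`)
#' disjoint from the source pattern's `?glycoconjugate_ref`, which
#' cross-joins when a graph holds several conjugates; `variant = "corrected"`
#' returns a version with the variables unified. All texts contain a live
#' SERVICE clause for the GlycoNAVI endpoint; pass them through
#' [rewrite_service()] (the `run_*` wrappers do this) to evaluate offline.
#'
#' @param name one of `"sites"`, `"glycans"`, `"diseases"`, `"publications"`,
#'   `"sources"`.
#' @param uniprot_id optional accession substituted into the query's
#'   `VALUES ?uniprot_id` clause (queries 3-5 carry one).
#' @param variant `"verbatim"` (default) or `"corrected"` (sources only).
#' @return SPARQL query text.
#' @export
canned_query <- function(name, uniprot_id = NULL,
                         variant = c("verbatim", "corrected")) {
  variant <- match.arg(variant)
  q <- switch(name,
              sites = .q_sites, glycans = .q_glycans, diseases = .q_diseases,
              publications = .q_publications, sources = .q_sources,
              stop("unknown query name '", name, "'; valid names: sites, ",
                   "glycans, diseases, publications, sources", call. = FALSE))
  if (variant == "corrected" && name == "sources") {
    q <- sub("\\?ref_conjugate gco:has_protein_part \\?ref_protein\\.",
             "?glycoconjugate_ref gco:has_protein_part ?protein_part.", q)
    q <- sub("\\?ref_protein gco:has_protein \\?protein \\.",
             "?protein_part gco:has_protein ?protein .", q)
  }
  if (!is.null(uniprot_id)) {
    if (!is_uniprot_accession(uniprot_id)) {
      stop("uniprot_id: not a valid UniProt accession: ", uniprot_id,
           call. = FALSE)
    }
    q <- gsub("VALUES \\?uniprot_id \\{\"[^\"]*\"\\}",
              sprintf("VALUES ?uniprot_id {\"%s\"}", uniprot_id), q)
  }
  q
}

# widen the published queries' VALUES ?g restrictions to the dataset's own
# named graphs, so the typed wrappers work on any dataset (e.g. the worked
# example's graph); on the three-database graphs this is a no-op for the
# result set since UNION branches deduplicate under DISTINCT
.expand_graph_values <- function(q, dataset) {
  gs <- graph_names(dataset)
  if (length(gs) == 0L) return(q)
  repl <- sprintf("VALUES ?g { %s }", paste0("<", gs, ">", collapse = " "))
  gsub("VALUES\\s*\\?g\\s*\\{[^}]*\\}", repl, q)
}

.run_canned <- function(dataset, name, uniprot_id, variant = "verbatim",
                        endpoints = .glyconavi_endpoint) {
  if (!is_uniprot_accession(uniprot_id)) {
    stop("uniprot_id: not a valid UniProt accession: ", uniprot_id,
         call. = FALSE)
  }
  q <- canned_query(name, uniprot_id = uniprot_id, variant = variant)
  q <- rewrite_service(q, endpoints)
  q <- .expand_graph_values(q, dataset)
  res <- sparql_select(dataset, q)
  res[!is.na(res$uniprot_id) & res$uniprot_id == uniprot_id, , drop = FALSE]
}

#' Run the canned integration queries for one protein
#'
#' Each wrapper evaluates the corresponding published query offline (SERVICE
#' clauses rewritten to the local dataset), restricts to the requested
#' accession, and returns typed rows in canonical order.
#'
#' @param dataset a `glyco_dataset`.
#' @param uniprot_id UniProt accession.
#' @return `run_sites`: data.frame(graph, uniprot_id, position) ordered by
#'   (graph, position), positions as integers.
#' @export
#' @examples
#' run_sites(fixture_worked_example(), "Q9EQH7")
run_sites <- function(dataset, uniprot_id) {
  res <- .run_canned(dataset, "sites", uniprot_id)
  out <- data.frame(graph = as.character(res$g),
                    uniprot_id = as.character(res$uniprot_id),
                    position = as.integer(res$site), stringsAsFactors = FALSE)
  out <- unique(out[order(out$graph, out$position, out$uniprot_id,
                          method = "radix"), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' @rdname run_sites
#' @return `run_glycans`: data.frame(graph, uniprot_id, glytoucan_id) ordered
#'   by (graph, uniprot_id, glytoucan_id).
#' @export
run_glycans <- function(dataset, uniprot_id) {
  res <- .run_canned(dataset, "glycans", uniprot_id)
  out <- data.frame(graph = as.character(res$g),
                    uniprot_id = as.character(res$uniprot_id),
                    glytoucan_id = as.character(res$glytoucan_id),
                    stringsAsFactors = FALSE)
  out <- unique(out[order(out$graph, out$uniprot_id, out$glytoucan_id,
                          method = "radix"), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' @rdname run_sites
#' @return `run_diseases`: data.frame(graph, disease_label, notation,
#'   uniprot_id); only diseases carrying both a label and a notation appear
#'   (both patterns are mandatory in the published query).
#' @export
run_diseases <- function(dataset, uniprot_id) {
  res <- .run_canned(dataset, "diseases", uniprot_id)
  out <- data.frame(graph = as.character(res$g),
                    disease_label = as.character(res$disease_label),
                    notation = as.character(res$notation),
                    uniprot_id = as.character(res$uniprot_id),
                    stringsAsFactors = FALSE)
  out <- unique(out[order(out$graph, out$disease_label, out$notation,
                          out$uniprot_id, method = "radix"), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' @rdname run_sites
#' @return `run_publications`: data.frame(graph, uniprot_id, pmid), pmid as
#'   integer; rows need both `glycan:has_pmid` and `dcterms:references`.
#' @export
run_publications <- function(dataset, uniprot_id) {
  res <- .run_canned(dataset, "publications", uniprot_id)
  out <- data.frame(graph = as.character(res$g),
                    uniprot_id = as.character(res$uniprot_id),
                    pmid = as.integer(res$PMID), stringsAsFactors = FALSE)
  out <- unique(out[order(out$graph, out$pmid, out$uniprot_id,
                          method = "radix"), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' @rdname run_sites
#' @param verbatim for `run_sources` only: evaluate the published query text
#'   exactly as printed (its GlycoNAVI branch can cross-join when a graph
#'   holds several conjugates); the default uses the variable-unified
#'   corrected variant, which matches the ground truth row-for-row.
#' @return `run_sources`: data.frame(graph, uniprot_id, tissue, cell_line,
#'   organism); tissue/cell_line/organism are `NA` when unbound (the
#'   published query wraps them in OPTIONAL, so rows are kept, not dropped).
#' @export
run_sources <- function(dataset, uniprot_id, verbatim = FALSE) {
  res <- .run_canned(dataset, "sources", uniprot_id,
                     variant = if (verbatim) "verbatim" else "corrected")
  out <- data.frame(graph = as.character(res$g),
                    uniprot_id = as.character(res$uniprot_id),
                    tissue = as.character(res$tissue),
                    cell_line = as.character(res$cell_line),
                    organism = as.character(res$organism),
                    stringsAsFactors = FALSE)
  key <- function(x) ifelse(is.na(x), "", x)
  out <- unique(out[order(out$graph, out$uniprot_id, key(out$tissue),
                          key(out$cell_line), key(out$organism),
                          method = "radix"), , drop = FALSE])
  rownames(out) <- NULL
  out
}

# ---- overlap ---------------------------------------------------------------

#' Cross-graph overlap summary
#'
#' Groups the values of one column of a query result by the set of named
#' graphs binding them, and partitions the values into common-to-all,
#' shared-by-some (more than one graph but not all), and unique-to-one. The
#' graph universe is the set of graphs occurring in `rows`. The three
#' partitions are disjoint and jointly exhaustive.
#'
#' @param rows data.frame with a `graph` column (any `run_*` output).
#' @param key name of the column whose values are compared across graphs.
#' @return object of class `overlap_summary`: list with `universe` (graphs),
#'   `membership` (named list: value -> sorted graph vector), and the
#'   partitions `common_to_all`, `shared_by_some`, `unique_to_one` (sorted
#'   character vectors).
#' @export
#' @examples
#' overlap_summary(run_sites(fixture_haptoglobin(), "P00738"), "position")
overlap_summary <- function(rows, key) {
  stopifnot(is.data.frame(rows), "graph" %in% names(rows), key %in% names(rows))
  rows <- rows[!is.na(rows[[key]]), , drop = FALSE]
  universe <- sort(unique(rows$graph), method = "radix")
  vals <- as.character(rows[[key]])
  membership <- lapply(split(rows$graph, vals),
                       function(g) sort(unique(g), method = "radix"))
  n_graphs <- vapply(membership, length, integer(1))
  all_vals <- sort(names(membership), method = "radix")
  n_graphs <- n_graphs[all_vals]
  structure(list(
    universe = universe,
    membership = membership[all_vals],
    common_to_all = if (length(universe) > 1L) {
      all_vals[n_graphs == length(universe)]
    } else character(0),
    shared_by_some = all_vals[n_graphs > 1L & n_graphs < length(universe)],
    unique_to_one = all_vals[n_graphs == 1L]
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %d value(s) across %d graph(s)\n",
              length(x$membership), length(x$universe)))
  cat("  common to all: ", paste(x$common_to_all, collapse = ", "), "\n")
  cat("  shared by some:", paste(x$shared_by_some, collapse = ", "), "\n")
  cat("  unique to one: ", paste(x$unique_to_one, collapse = ", "), "\n")
  invisible(x)
}
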