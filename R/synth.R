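# Seeded generator of arbitrary-size schema-conformant datasets with a
# ground-truth table per query family. Every entity is emitted through the
# model builders, so generator output is the oracle for the query engine:
# whatever was generated must come back, row for row, from the five canned
# queries.

#' Parameters for the synthetic dataset generator
#'
#' @param n_proteins number of distinct proteins (>= 0). Each protein is
#'   assigned to a random non-empty subset of the graphs, with an independent
#'   record per graph, so cross-graph overlap is non-trivial.
#' @param sites_per_protein integer range (length 2) of glycosylation sites
#'   drawn per record.
#' @param glycans_per_site integer range of glycans drawn per site; the draws
#'   are pooled per record (sites and glycans stay independent, as in
#'   partially site-resolved data).
#' @param graph_names character vector of graph IRIs.
#' @param diseases,citations,sources,abundances logical richness flags.
#' @param seed integer seed; the same seed yields byte-identical datasets and
#'   ground truth.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(n_proteins = 20L,
                         sites_per_protein = c(1L, 5L),
                         glycans_per_site = c(0L, 4L),
                         graph_names = c(.g_glyconnect, .g_unicarbkb,
                                         .g_glyconavi),
                         diseases = TRUE, citations = TRUE, sources = TRUE,
                         abundances = TRUE, seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  sites_per_protein <- as.integer(sites_per_protein)
  glycans_per_site <- as.integer(glycans_per_site)
  if (is.na(n_proteins) || n_proteins < 0L) {
    stop("n_proteins must be a non-negative integer", call. = FALSE)
  }
  for (r in list(sites_per_protein, glycans_per_site)) {
    if (length(r) != 2L || anyNA(r) || r[1] < 0L || r[2] < r[1]) {
      stop("ranges must be c(lo, hi) with 0 <= lo <= hi", call. = FALSE)
    }
  }
  if (length(graph_names) < 1L) stop("need at least one graph", call. = FALSE)
  structure(list(n_proteins = n_proteins,
                 sites_per_protein = sites_per_protein,
                 glycans_per_site = glycans_per_site,
                 graph_names = graph_names,
                 diseases = isTRUE(diseases), citations = isTRUE(citations),
                 sources = isTRUE(sources), abundances = isTRUE(abundances),
                 seed = as.integer(seed)),
            class = "synth_params")
}

.disease_pool <- data.frame(
  label = paste0("synthetic disease ", 1:8),
  notation = sprintf("SYN:S%04d", 1:8),
  stringsAsFactors = FALSE)

.taxon_pool <- data.frame(
  taxon = paste0("http://purl.uniprot.org/taxonomy/", c(9606, 10090, 10116)),
  organism = c("Homo sapiens", "Mus musculus", "Rattus norvegicus"),
  stringsAsFactors = FALSE)

#' Generate a synthetic conformant dataset with ground truth
#'
#' Draws proteins, per-graph site/glycan/metadata records under `params`,
#' emits everything through [build_conjugate()], and records exactly what was
#' generated as five data.frames mirroring the outputs of [run_sites()],
#' [run_glycans()], [run_diseases()], [run_publications()] and
#' [run_sources()]. The RNG state of the session is left untouched.
#'
#' @param params a [synth_params()] object.
#' @return list with elements `dataset` (a `glyco_dataset`) and `truth`
#'   (list of data.frames: `sites`, `glycans`, `diseases`, `publications`,
#'   `sources`).
#' @export
#' @examples
#' out <- synth_dataset(synth_params(n_proteins = 2, seed = 42))
#' out$truth$sites
synth_dataset <- function(params = synth_params()) {
  if (!inherits(params, "synth_params")) {
    stop("params must come from synth_params()", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(params$seed)

  ds <- new_dataset()
  truth <- list(
    sites = data.frame(graph = character(0), uniprot_id = character(0),
                       position = integer(0), stringsAsFactors = FALSE),
    glycans = data.frame(graph = character(0), uniprot_id = character(0),
                         glytoucan_id = character(0), stringsAsFactors = FALSE),
    diseases = data.frame(graph = character(0), disease_label = character(0),
                          notation = character(0), uniprot_id = character(0),
                          stringsAsFactors = FALSE),
    publications = data.frame(graph = character(0), uniprot_id = character(0),
                              pmid = integer(0), stringsAsFactors = FALSE),
    sources = data.frame(graph = character(0), uniprot_id = character(0),
                         tissue = character(0), cell_line = character(0),
                         organism = character(0), stringsAsFactors = FALSE))
  if (params$n_proteins == 0L) {
    return(list(dataset = ds, truth = truth))
  }

  rint <- function(range) {
    if (range[1] == range[2]) range[1]
    else sample(range[1]:range[2], 1L)
  }
  accessions <- sprintf("P%05d", seq_len(params$n_proteins))
  # shared glycan pool so accessions recur across graphs/proteins
  pool_size <- max(4L, params$n_proteins)
  glycan_pool <- sprintf("G%05d%s", seq_len(pool_size),
                         paste0(sample(LETTERS, pool_size, replace = TRUE),
                                sample(LETTERS, pool_size, replace = TRUE)))

  for (i in seq_len(params$n_proteins)) {
    u <- accessions[i]
    n_g <- sample(seq_along(params$graph_names), 1L)
    graphs <- sample(params$graph_names, n_g)
    for (g in sort(graphs, method = "radix")) {
      n_sites <- rint(params$sites_per_protein)
      sites <- if (n_sites > 0L) sort(sample(1:600, n_sites)) else integer(0)
      n_gly <- sum(vapply(seq_len(max(n_sites, 1L)),
                          function(k) rint(params$glycans_per_site),
                          integer(1)))
      gly_ids <- if (n_gly > 0L) {
        sort(unique(sample(glycan_pool, min(n_gly, pool_size))))
      } else character(0)
      glycans <- data.frame(
        glytoucan_id = gly_ids,
        abundance = if (params$abundances && length(gly_ids) > 0L) {
          ifelse(stats::runif(length(gly_ids)) < 0.5,
                 round(stats::runif(length(gly_ids)), 2), NA_real_)
        } else rep(NA_real_, length(gly_ids)),
        stringsAsFactors = FALSE)

      dis <- if (params$diseases && stats::runif(1) < 0.8) {
        .disease_pool[sample(nrow(.disease_pool),
                             sample(0:2, 1L, prob = c(.2, .5, .3))), ,
                      drop = FALSE]
      } else .disease_pool[0, , drop = FALSE]
      pmids <- if (params$citations && stats::runif(1) < 0.8) {
        sort(sample(10000000:30000000, sample(0:3, 1L)))
      } else integer(0)

      taxon <- organism <- tissue <- cell_line <- NULL
      if (params$sources) {
        # named taxa always carry up:scientificName; the nameless case uses
        # the 'unidentified' taxon so a name attached by another record to a
        # shared taxon IRI cannot leak into this record's rows
        if (stats::runif(1) < 0.8) {
          tx <- .taxon_pool[sample(nrow(.taxon_pool), 1L), ]
          taxon <- tx$taxon
          organism <- tx$organism
        } else {
          taxon <- "http://purl.uniprot.org/taxonomy/32644"
        }
        if (stats::runif(1) < 0.5) {
          tissue <- paste0(.synth_ns, "tissue/tissue-", sample(5, 1L))
        }
        if (stats::runif(1) < 0.5) {
          cell_line <- paste0(.synth_ns, "cell-line/cell-line-", sample(5, 1L))
        }
      }

      rec <- glyco_record(u, sites = sites, glycans = glycans,
                          taxon = taxon, organism = organism,
                          tissue = tissue, cell_line = cell_line,
                          diseases = dis, pmids = pmids)
      build_conjugate(ds, g, rec)

      if (length(rec$sites) > 0L) {
        truth$sites <- rbind(truth$sites, data.frame(
          graph = g, uniprot_id = u, position = rec$sites,
          stringsAsFactors = FALSE))
      }
      if (nrow(rec$glycans) > 0L) {
        truth$glycans <- rbind(truth$glycans, data.frame(
          graph = g, uniprot_id = u, glytoucan_id = rec$glycans$glytoucan_id,
          stringsAsFactors = FALSE))
      }
      if (nrow(rec$diseases) > 0L) {
        truth$diseases <- rbind(truth$diseases, data.frame(
          graph = g, disease_label = rec$diseases$label,
          notation = rec$diseases$notation, uniprot_id = u,
          stringsAsFactors = FALSE))
      }
      if (length(rec$pmids) > 0L) {
        truth$publications <- rbind(truth$publications, data.frame(
          graph = g, uniprot_id = u, pmid = rec$pmids,
          stringsAsFactors = FALSE))
      }
      if (!is.null(taxon)) {
        truth$sources <- rbind(truth$sources, data.frame(
          graph = g, uniprot_id = u,
          tissue = if (is.null(tissue)) NA_character_ else tissue,
          cell_line = if (is.null(cell_line)) NA_character_ else cell_line,
          organism = if (is.null(organism)) NA_character_ else organism,
          stringsAsFactors = FALSE))
      }
    }
  }

  # canonical row order mirroring the run_* wrappers
  ord <- function(df, cols) {
    keys <- lapply(df[cols], function(x) {
      if (is.character(x)) ifelse(is.na(x), "", x) else x
    })
    df <- df[do.call(order, c(keys, list(method = "radix"))), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  truth$sites <- ord(truth$sites, c("graph", "position", "uniprot_id"))
  truth$glycans <- ord(truth$glycans, c("graph", "uniprot_id", "glytoucan_id"))
  truth$diseases <- ord(truth$diseases,
                        c("graph", "disease_label", "notation", "uniprot_id"))
  truth$publications <- ord(truth$publications,
                            c("graph", "pmid", "uniprot_id"))
  truth$sources <- ord(truth$sources,
                       c("graph", "uniprot_id", "tissue", "cell_line",
                         "organism"))
  list(dataset = ds, truth = truth)
}
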