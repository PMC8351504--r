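#' Create an empty named-graph RDF dataset
#'
#' A dataset is a mutable store of quads: a default graph plus any number of
#' named graphs, each holding a duplicate-free set of triples. It is the unit
#' of storage for all builders, serializers, validators and queries in the
#' package. Datasets are environment-backed, so builder functions insert
#' triples in place.
#'
#' @return An object of class `glyco_dataset` with zero graphs and triples.
#' @export
#' @examples
#' ds <- new_dataset()
#' triple_count(ds)
new_dataset <- function() {
  e <- new.env(parent = emptyenv())
  e$g <- character(0)
  e$s <- character(0)
  e$p <- character(0)
  e$o <- character(0)
  e$key <- character(0)
  class(e) <- "glyco_dataset"
  e
}

# insert encoded quads, silently dropping duplicates; g == "" is the default
# graph
add_quads <- function(ds, g, s, p, o) {
  stopifnot(inherits(ds, "glyco_dataset"))
  n <- max(length(g), length(s), length(p), length(o))
  if (n == 0L) return(invisible(ds))
  g <- rep_len(as.character(g), n)
  s <- rep_len(as.character(s), n)
  p <- rep_len(as.character(p), n)
  o <- rep_len(as.character(o), n)
  key <- paste(g, s, p, o, sep = "\r")
  keep <- !duplicated(key) & !(key %in% ds$key)
  if (any(keep)) {
    ds$g <- c(ds$g, g[keep])
    ds$s <- c(ds$s, s[keep])
    ds$p <- c(ds$p, p[keep])
    ds$o <- c(ds$o, o[keep])
    ds$key <- c(ds$key, key[keep])
  }
  invisible(ds)
}

remove_quads <- function(ds, idx) {
  stopifnot(inherits(ds, "glyco_dataset"))
  if (length(idx) == 0L) return(invisible(ds))
  ds$g <- ds$g[-idx]; ds$s <- ds$s[-idx]
  ds$p <- ds$p[-idx]; ds$o <- ds$o[-idx]
  ds$key <- ds$key[-idx]
  invisible(ds)
}

#' Quads of a dataset as a data.frame
#'
#' @param ds a `glyco_dataset`.
#' @return data.frame with columns `graph`, `subject`, `predicate`, `object`
#'   holding N-Triples-encoded terms; `graph` is `""` for the default graph.
#' @export
dataset_quads <- function(ds) {
  stopifnot(inherits(ds, "glyco_dataset"))
  data.frame(graph = ds$g, subject = ds$s, predicate = ds$p, object = ds$o,
             stringsAsFactors = FALSE)
}

#' Names of the named graphs in a dataset
#'
#' @param ds a `glyco_dataset`.
#' @return sorted character vector of graph IRIs (decoded, without `<>`).
#' @export
graph_names <- function(ds) {
  stopifnot(inherits(ds, "glyco_dataset"))
  g <- unique(ds$g)
  g <- g[g != ""]
  sort(term_str(g), method = "radix")
}

#' Number of triples in a dataset
#'
#' @param ds a `glyco_dataset`.
#' @param graph optional graph IRI (decoded string) restricting the count.
#' @return integer triple count.
#' @export
triple_count <- function(ds, graph = NULL) {
  stopifnot(inherits(ds, "glyco_dataset"))
  if (is.null(graph)) return(length(ds$s))
  sum(ds$g == iri(graph))
}

#' Test two datasets for equality of their triple sets
#'
#' Equality is per-graph set equality of triples; insertion order and
#' serialization history are irrelevant.
#'
#' @param a,b `glyco_dataset` objects.
#' @return TRUE if both datasets hold the same quads.
#' @export
datasets_equal <- function(a, b) {
  setequal(a$key, b$key)
}

#' Merge datasets into one
#'
#' Graphs with the same name are unioned; duplicates are dropped.
#'
#' @param ... `glyco_dataset` objects.
#' @return a new `glyco_dataset`.
#' @export
merge_datasets <- function(...) {
  out <- new_dataset()
  for (ds in list(...)) {
    stopifnot(inherits(ds, "glyco_dataset"))
    add_quads(out, ds$g, ds$s, ds$p, ds$o)
  }
  out
}

#' @export
print.glyco_dataset <- function(x, ...) {
  gs <- graph_names(x)
  cat(sprintf("<glyco_dataset> %d triples, %d named graph(s)\n",
              triple_count(x), length(gs)))
  for (g in gs) cat(sprintf("  <%s>: %d triples\n", g, sum(x$g == iri(g))))
  ndef <- sum(x$g == "")
  if (ndef > 0L) cat(sprintf("  (default graph): %d triples\n", ndef))
  invisible(x)
}
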