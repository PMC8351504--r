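# RDF terms are carried everywhere as N-Triples-encoded character strings:
#   "<http://...>"                      IRI
#   "\"lexical\""                       plain literal (== xsd:string)
#   "\"lexical\"^^<datatype-iri>"       typed literal
#   "\"lexical\"@en"                    language-tagged literal
#   "_:label"                           blank node (accepted on parse only)
# The encoding is canonical (fixed escaping, xsd:string collapsed to plain),
# so term equality is plain string equality and triple sets can be stored,
# deduplicated and sorted as character vectors.

#' Namespace table used by the toolkit
#'
#' Prefix-to-namespace mapping covering every vocabulary the GlycoCoO query
#' patterns draw from (gco, glycan, faldo, sio, dcterms, foaf, skos, rdfs,
#' up), the RDF/XSD base vocabularies, and the package's extension namespace
#' `gcx` used for the two relations the ontology names but does not print a
#' predicate for (glycan abundance ratios, lipid parts).
#'
#' @return A data.frame with columns `prefix` and `namespace`.
#' @export
#' @examples
#' vocabulary()
vocabulary <- function() {
  data.frame(prefix = names(.gco_prefixes), namespace = unname(.gco_prefixes),
             stringsAsFactors = FALSE)
}

.gco_prefixes <- c(
  gco     = "http://purl.jp/bio/12/glyco/conjugate#",
  glycan  = "http://purl.jp/bio/12/glyco/glycan#",
  faldo   = "http://biohackathon.org/resource/faldo#",
  sio     = "http://semanticscience.org/resource/",
  dcterms = "http://purl.org/dc/terms/",
  foaf    = "http://xmlns.com/foaf/0.1/",
  skos    = "http://www.w3.org/2008/05/skos#",
  rdfs    = "http://www.w3.org/2000/01/rdf-schema#",
  up      = "http://purl.uniprot.org/core/",
  rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  xsd     = "http://www.w3.org/2001/XMLSchema#",
  gcx     = "http://glycoinfo.org/glycocoo/extension#"
)

# prefixes the SPARQL evaluator supplies when a query omits them; the
# printed queries use rdfs:seeAlso without declaring rdfs
.builtin_query_prefixes <- .gco_prefixes[c("rdf", "rdfs", "xsd")]

#' Construct an IRI term
#'
#' @param x character vector of absolute IRIs (must carry a scheme).
#' @return encoded IRI terms (`"<iri>"`).
#' @export
iri <- function(x) {
  x <- as.character(x)
  bad <- !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) | grepl("[<>\" {}|\\^`\\\\]", x)
  if (any(bad)) {
    stop("not an absolute IRI: ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  paste0("<", x, ">")
}

# expand prefix:local against a named namespace vector
curie <- function(x, prefixes = .gco_prefixes) {
  pre <- sub(":.*$", "", x)
  loc <- sub("^[^:]*:", "", x)
  ns <- prefixes[pre]
  if (anyNA(ns)) {
    stop("undeclared prefix: ", paste(unique(pre[is.na(ns)]), collapse = ", "),
         call. = FALSE)
  }
  paste0("<", ns, loc, ">")
}

.escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.unescape_literal <- function(x) {
  # reverse of .escape_literal plus \uXXXX
  out <- vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    res <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        rep <- switch(nxt,
                      "n" = "\n", "r" = "\r", "t" = "\t", "b" = "\b",
                      "f" = "\f", "\"" = "\"", "'" = "'", "\\" = "\\",
                      NULL)
        if (!is.null(rep)) {
          res <- c(res, rep); i <- i + 2L; next
        }
        if (nxt == "u" && i + 5L <= length(chars)) {
          code <- paste(chars[(i + 2L):(i + 5L)], collapse = "")
          res <- c(res, intToUtf8(strtoi(code, 16L))); i <- i + 6L; next
        }
        if (nxt == "U" && i + 9L <= length(chars)) {
          code <- paste(chars[(i + 2L):(i + 9L)], collapse = "")
          res <- c(res, intToUtf8(strtoi(code, 16L))); i <- i + 10L; next
        }
      }
      res <- c(res, ch); i <- i + 1L
    }
    paste(res, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out
}

.xsd <- function(local) paste0("<http://www.w3.org/2001/XMLSchema#", local, ">")

#' Construct literal terms
#'
#' `lit_string`, `lit_integer` and `lit_decimal` build canonically encoded
#' plain, xsd:integer and xsd:decimal literals.
#'
#' @param x values to encode.
#' @return encoded literal terms.
#' @export
lit_string <- function(x) paste0("\"", .escape_literal(as.character(x)), "\"")

#' @rdname lit_string
#' @export
lit_integer <- function(x) {
  x <- as.integer(x)
  if (anyNA(x)) stop("non-integer value for integer literal", call. = FALSE)
  paste0("\"", x, "\"^^", .xsd("integer"))
}

#' @rdname lit_string
#' @export
lit_decimal <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("non-numeric value for decimal literal", call. = FALSE)
  lex <- sub("0+$", "", sprintf("%.6f", x))
  lex <- sub("\\.$", ".0", lex)
  paste0("\"", lex, "\"^^", .xsd("decimal"))
}

# ---- term inspection -------------------------------------------------------

term_kind <- function(t) {
  out <- rep(NA_character_, length(t))
  out[startsWith(t, "<")] <- "iri"
  out[startsWith(t, "\"")] <- "literal"
  out[startsWith(t, "_:")] <- "blank"
  out
}

# lexical form of a literal / IRI string of an IRI (SPARQL str() semantics)
term_str <- function(t) {
  out <- t
  is_iri <- !is.na(t) & startsWith(t, "<")
  out[is_iri] <- substr(t[is_iri], 2L, nchar(t[is_iri]) - 1L)
  is_lit <- !is.na(t) & startsWith(t, "\"")
  if (any(is_lit)) {
    lex <- sub("^\"(.*)\"(\\^\\^<[^>]*>|@[A-Za-z0-9-]+)?$", "\\1", t[is_lit])
    out[is_lit] <- .unescape_literal(lex)
  }
  out
}

term_datatype <- function(t) {
  dt <- rep(NA_character_, length(t))
  m <- regmatches(t, regexpr("\\^\\^<[^>]*>$", t))
  has <- grepl("\\^\\^<[^>]*>$", t)
  dt[has] <- substr(m, 4L, nchar(m) - 1L)
  dt
}

# numeric value of integer/decimal literals, NA otherwise
term_numeric <- function(t) {
  dt <- term_datatype(t)
  num <- !is.na(dt) & dt %in% paste0("http://www.w3.org/2001/XMLSchema#",
                                     c("integer", "decimal", "double", "float"))
  out <- rep(NA_real_, length(t))
  out[num] <- suppressWarnings(as.numeric(term_str(t[num])))
  out
}
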