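# Reading and writing named-graph datasets in Turtle, TriG and N-Quads.
# The writer is canonical: prefixes from vocabulary() only, graphs and triples
# sorted bytewise, one triple per line. Canonical output is a fixpoint of
# parse/write, which keeps fixtures diff-stable.

.norm_format <- function(format) {
  f <- tolower(format[1])
  f <- c(ttl = "turtle", turtle = "turtle", trig = "trig",
         nq = "nquads", nquads = "nquads", "n-quads" = "nquads")[f]
  if (is.na(f)) stop("unknown RDF format: ", format, call. = FALSE)
  f
}

#' Parse an RDF document into a dataset
#'
#' Supports Turtle (single graph), TriG and N-Quads. `source` is a file path
#' if a file by that name exists, otherwise it is taken to be the document
#' text itself.
#'
#' @param source path to a file, or document text.
#' @param format one of `"turtle"`, `"trig"`, `"nquads"` (aliases `ttl`, `nq`
#'   accepted).
#' @param graph for Turtle input, optional graph IRI the parsed triples are
#'   placed under; by default they go to the default graph.
#' @return a `glyco_dataset`.
#' @export
#' @examples
#' ds <- parse_dataset("<http://a/s> <http://a/p> \"x\" .", "turtle")
#' triple_count(ds)
parse_dataset <- function(source, format, graph = NULL) {
  format <- .norm_format(format)
  text <- if (length(source) == 1L && !grepl("\n", source) &&
              file.exists(source)) {
    paste(readLines(source, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  toks <- tokenize_rdf(text)
  cu <- new_cursor(toks)
  if (format == "nquads") return(.parse_nquads(cu))
  .parse_trig(cu, turtle_only = (format == "turtle"), turtle_graph = graph)
}

# ---- term reading ----------------------------------------------------------

.read_term <- function(cu, prefixes, allow_literal = TRUE) {
  t <- cur_next(cu)
  if (t$type == "IRIREF") return(t$text)
  if (t$type == "PNAME") return(curie(t$text, prefixes))
  if (t$type == "BLANK") return(t$text)
  if (t$type == "WORD" && t$text == "a") {
    return(paste0("<", .gco_prefixes[["rdf"]], "type>"))
  }
  if (!allow_literal) {
    stop(sprintf("syntax error: expected IRI at line %s, column %s (found '%s')",
                 t$line, t$col, t$text), call. = FALSE)
  }
  if (t$type == "STRING") {
    lex <- t$text
    nxt <- cur_peek(cu)
    if (nxt$type == "DTYPE") {
      cur_next(cu)
      dt <- cur_next(cu)
      dt_iri <- if (dt$type == "IRIREF") dt$text
                else if (dt$type == "PNAME") curie(dt$text, prefixes)
                else stop("syntax error: bad datatype at line ", dt$line,
                          call. = FALSE)
      if (dt_iri == .xsd("string")) return(lex)  # normalize to plain
      return(paste0(lex, "^^", dt_iri))
    }
    if (nxt$type == "AT") {
      cur_next(cu)
      return(paste0(lex, tolower(nxt$text)))
    }
    return(lex)
  }
  if (t$type == "NUMBER") {
    if (grepl("[.eE]", t$text)) return(paste0("\"", t$text, "\"^^", .xsd("decimal")))
    return(paste0("\"", t$text, "\"^^", .xsd("integer")))
  }
  stop(sprintf("syntax error: unexpected token '%s' at line %s, column %s",
               t$text, t$line, t$col), call. = FALSE)
}

# predicate-object list for one subject; returns list(p=chr, o=chr)
.read_po_list <- function(cu, prefixes) {
  ps <- character(0); os <- character(0)
  repeat {
    p <- .read_term(cu, prefixes, allow_literal = FALSE)
    repeat {
      o <- .read_term(cu, prefixes, allow_literal = TRUE)
      ps <- c(ps, p); os <- c(os, o)
      if (cur_peek(cu)$text == ",") { cur_next(cu); next }
      break
    }
    if (cur_peek(cu)$text == ";") {
      cur_next(cu)
      # tolerate trailing ';' before '.' or '}'
      if (cur_peek(cu)$text %in% c(".", "}")) break
      next
    }
    break
  }
  list(p = ps, o = os)
}

.parse_trig <- function(cu, turtle_only = FALSE, turtle_graph = NULL) {
  ds <- new_dataset()
  prefixes <- character(0)
  default_g <- if (!is.null(turtle_graph)) iri(turtle_graph) else ""

  read_triples_block <- function(gname) {
    # inside '{ ... }'
    repeat {
      t <- cur_peek(cu)
      if (t$text == "}") { cur_next(cu); break }
      if (t$type == "EOF") cur_stop(cu, "unterminated graph block")
      s <- .read_term(cu, prefixes, allow_literal = FALSE)
      po <- .read_po_list(cu, prefixes)
      add_quads(ds, gname, s, po$p, po$o)
      if (cur_peek(cu)$text == ".") cur_next(cu)
    }
  }

  repeat {
    t <- cur_peek(cu)
    if (t$type == "EOF") break
    low <- tolower(t$text)
    if (t$type == "AT" && low == "@prefix") {
      cur_next(cu)
      pn <- cur_expect(cu, type = "PNAME")
      ir <- cur_expect(cu, type = "IRIREF")
      cur_expect(cu, text = ".")
      prefixes[sub(":.*$", "", pn$text)] <- substr(ir$text, 2L, nchar(ir$text) - 1L)
      next
    }
    if (t$type == "WORD" && low == "prefix") {
      cur_next(cu)
      pn <- cur_expect(cu, type = "PNAME")
      ir <- cur_expect(cu, type = "IRIREF")
      prefixes[sub(":.*$", "", pn$text)] <- substr(ir$text, 2L, nchar(ir$text) - 1L)
      next
    }
    if (t$type == "AT" || (t$type == "WORD" && low == "base")) {
      cur_stop(cu, "unsupported directive")
    }
    if (t$type == "WORD" && low == "graph") {
      if (turtle_only) cur_stop(cu, "named graph block in Turtle input")
      cur_next(cu)
      g <- .read_term(cu, prefixes, allow_literal = FALSE)
      cur_expect(cu, text = "{")
      read_triples_block(g)
      next
    }
    if (t$text == "{") {  # anonymous default-graph block (TriG)
      if (turtle_only) cur_stop(cu, "graph block in Turtle input")
      cur_next(cu)
      read_triples_block(default_g)
      next
    }
    # either a named graph block "<g> { ... }" or a plain triple statement
    s <- .read_term(cu, prefixes, allow_literal = FALSE)
    if (cur_peek(cu)$text == "{") {
      if (turtle_only) cur_stop(cu, "named graph block in Turtle input")
      cur_next(cu)
      read_triples_block(s)
      next
    }
    po <- .read_po_list(cu, prefixes)
    add_quads(ds, default_g, s, po$p, po$o)
    cur_expect(cu, text = ".")
  }
  ds
}

.parse_nquads <- function(cu) {
  ds <- new_dataset()
  repeat {
    if (cur_eof(cu)) break
    s <- .read_term(cu, character(0), allow_literal = FALSE)
    p <- .read_term(cu, character(0), allow_literal = FALSE)
    o <- .read_term(cu, character(0), allow_literal = TRUE)
    g <- ""
    if (cur_peek(cu)$text != ".") {
      g <- .read_term(cu, character(0), allow_literal = FALSE)
    }
    cur_expect(cu, text = ".")
    add_quads(ds, g, s, p, o)
  }
  ds
}

# ---- writing ---------------------------------------------------------------

# render an encoded term with prefixed names where safe; vectorized
.render_term <- function(t, use_prefixes = TRUE) {
  out <- t
  if (!use_prefixes) return(out)
  is_iri <- startsWith(t, "<")
  if (any(is_iri)) {
    v <- term_str(t[is_iri])
    rendered <- t[is_iri]
    for (pre in names(.gco_prefixes)) {
      ns <- .gco_prefixes[[pre]]
      hit <- startsWith(v, ns)
      if (!any(hit)) next
      loc <- substr(v[hit], nchar(ns) + 1L, nchar(v[hit]))
      ok <- grepl("^[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?$", loc,
                  perl = TRUE) & !grepl("[/#]", loc)
      idx <- which(hit)[ok]
      rendered[idx] <- paste0(pre, ":", loc[ok])
    }
    out[is_iri] <- rendered
  }
  # literals: compact the datatype IRI for known namespaces
  has_dt <- grepl("\\^\\^<", t)
  if (any(has_dt)) {
    dt <- term_datatype(t[has_dt])
    lex <- sub("\\^\\^<[^>]*>$", "", t[has_dt])
    dtr <- .render_term(paste0("<", dt, ">"), use_prefixes = TRUE)
    out[has_dt] <- paste0(lex, "^^", dtr)
  }
  out
}

.prefix_block <- function(terms, style = c("turtle", "trig")) {
  style <- match.arg(style)
  used <- vapply(names(.gco_prefixes), function(pre) {
    any(startsWith(terms, paste0(pre, ":")) |
          grepl(paste0("\\^\\^", pre, ":"), terms, fixed = FALSE))
  }, logical(1))
  pre <- names(.gco_prefixes)[used]
  if (length(pre) == 0L) return(character(0))
  pre <- sort(pre, method = "radix")
  c(sprintf("@prefix %s: <%s> .", pre, .gco_prefixes[pre]), "")
}

#' Serialize a dataset
#'
#' Output is canonical: graphs and triples sorted bytewise, prefix
#' declarations restricted to the package vocabulary, one triple per line.
#' Writing the same dataset twice yields byte-identical documents, and
#' write-parse-write is a fixpoint.
#'
#' @param ds a `glyco_dataset`.
#' @param format `"turtle"` (single graph only), `"trig"`, or `"nquads"`.
#' @param file optional path to write to.
#' @param graph for Turtle, the graph to serialize when the dataset has more
#'   than one (decoded IRI string).
#' @return the document as a single character string, invisibly when `file`
#'   is given.
#' @export
write_dataset <- function(ds, format, file = NULL, graph = NULL) {
  stopifnot(inherits(ds, "glyco_dataset"))
  format <- .norm_format(format)
  q <- dataset_quads(ds)

  doc <- if (format == "nquads") {
    ord <- order(q$graph, q$subject, q$predicate, q$object, method = "radix")
    q <- q[ord, , drop = FALSE]
    lines <- if (nrow(q) == 0L) character(0) else {
      gpart <- ifelse(q$graph == "", "", paste0(q$graph, " "))
      paste0(q$subject, " ", q$predicate, " ", q$object, " ", gpart, ".")
    }
    paste(c(lines, ""), collapse = "\n")
  } else if (format == "turtle") {
    gs <- unique(q$graph)
    if (!is.null(graph)) {
      q <- q[q$graph == iri(graph), , drop = FALSE]
    } else if (length(gs) > 1L) {
      stop("turtle output requires a single-graph dataset or graph=",
           call. = FALSE)
    }
    q <- q[order(q$subject, q$predicate, q$object, method = "radix"), ,
           drop = FALSE]
    s <- .render_term(q$subject); p <- .render_term(q$predicate)
    o <- .render_term(q$object)
    lines <- if (nrow(q) == 0L) character(0) else paste0(s, " ", p, " ", o, " .")
    paste(c(.prefix_block(c(s, p, o)), lines, ""), collapse = "\n")
  } else {  # trig
    q <- q[order(q$graph, q$subject, q$predicate, q$object, method = "radix"), ,
           drop = FALSE]
    s <- .render_term(q$subject); p <- .render_term(q$predicate)
    o <- .render_term(q$object)
    body <- character(0)
    default <- q$graph == ""
    if (any(default)) {
      body <- c(body, paste0(s[default], " ", p[default], " ",
                             o[default], " ."), "")
    }
    for (g in unique(q$graph[!default])) {
      in_g <- q$graph == g
      body <- c(body, paste0(g, " {"),
                paste0("    ", s[in_g], " ", p[in_g], " ", o[in_g], " ."),
                "}", "")
    }
    if (length(body) > 0L && body[length(body)] == "") {
      body <- body[-length(body)]
    }
    paste(c(.prefix_block(c(s, p, o)), body, ""), collapse = "\n")
  }

  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(doc)), con)
    return(invisible(doc))
  }
  doc
}
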