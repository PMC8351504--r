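# A SPARQL 1.1 SELECT evaluator covering the fragment the GlycoCoO canned
# queries use: basic graph patterns with ';'/',' abbreviations, GRAPH,
# nested group/OPTIONAL/UNION, single-variable inline VALUES, DISTINCT,
# str() projection expressions, ORDER BY, and SERVICE clauses handled by
# local rewriting (rewrite_service). Solutions are data.frames of encoded
# terms with NA for unbound variables; joins use SPARQL compatibility
# (unbound is compatible with anything).

# ---- parsing ---------------------------------------------------------------

.parse_sparql <- function(text) {
  cu <- new_cursor(tokenize_rdf(text))
  prefixes <- character(0)

  # prologue
  repeat {
    t <- cur_peek(cu)
    if (t$type %in% c("WORD", "AT") &&
        tolower(sub("^@", "", t$text)) == "prefix") {
      cur_next(cu)
      pn <- cur_expect(cu, type = "PNAME")
      ir <- cur_expect(cu, type = "IRIREF")
      prefixes[sub(":.*$", "", pn$text)] <-
        substr(ir$text, 2L, nchar(ir$text) - 1L)
      if (cur_peek(cu)$text == ".") cur_next(cu)
      next
    }
    break
  }
  for (pre in names(.builtin_query_prefixes)) {
    if (!(pre %in% names(prefixes))) {
      prefixes[pre] <- .builtin_query_prefixes[[pre]]
    }
  }

  cur_expect(cu, text = "select")
  distinct <- FALSE
  if (tolower(cur_peek(cu)$text) == "distinct") { cur_next(cu); distinct <- TRUE }
  if (tolower(cur_peek(cu)$text) == "reduced") { cur_next(cu) }

  items <- list()
  star <- FALSE
  repeat {
    t <- cur_peek(cu)
    if (t$text == "*") { cur_next(cu); star <- TRUE; next }
    if (t$type == "VAR") {
      cur_next(cu)
      items[[length(items) + 1L]] <- list(kind = "var",
                                          var = sub("^\\?", "", t$text))
      next
    }
    if (t$text == "(") {
      cur_next(cu)
      fn <- cur_next(cu)
      if (tolower(fn$text) != "str") cur_stop(cu, "unsupported expression")
      cur_expect(cu, text = "(")
      v <- cur_expect(cu, type = "VAR")
      cur_expect(cu, text = ")")
      as_t <- cur_next(cu)
      if (tolower(as_t$text) != "as") cur_stop(cu, "expected AS")
      alias <- cur_expect(cu, type = "VAR")
      cur_expect(cu, text = ")")
      items[[length(items) + 1L]] <- list(kind = "str",
                                          var = sub("^\\?", "", v$text),
                                          alias = sub("^\\?", "", alias$text))
      next
    }
    break
  }
  if (!star && length(items) == 0L) cur_stop(cu, "empty SELECT clause")

  if (tolower(cur_peek(cu)$text) == "where") cur_next(cu)
  where <- .parse_group(cu, prefixes)

  order_by <- character(0)
  if (tolower(cur_peek(cu)$text) == "order") {
    cur_next(cu)
    cur_expect(cu, text = "by")
    repeat {
      t <- cur_peek(cu)
      if (t$type == "VAR") {
        cur_next(cu)
        order_by <- c(order_by, sub("^\\?", "", t$text))
        next
      }
      break
    }
  }
  if (!cur_eof(cu)) cur_stop(cu, "trailing content after query")

  list(prefixes = prefixes, distinct = distinct, star = star, items = items,
       where = where, order_by = order_by)
}

.pattern_term <- function(cu, prefixes, allow_literal = TRUE) {
  t <- cur_peek(cu)
  if (t$type == "VAR") {
    cur_next(cu)
    return(list(var = sub("^\\?", "", t$text)))
  }
  list(term = .read_term(cu, prefixes, allow_literal))
}

# group graph pattern: returns list(type="group", parts=list(...))
.parse_group <- function(cu, prefixes) {
  cur_expect(cu, text = "{")
  parts <- list()
  repeat {
    t <- cur_peek(cu)
    low <- tolower(t$text)
    if (t$text == "}") { cur_next(cu); break }
    if (t$type == "EOF") cur_stop(cu, "unterminated group")
    if (t$text == "{") {
      node <- .parse_group(cu, prefixes)
      while (tolower(cur_peek(cu)$text) == "union") {
        cur_next(cu)
        rhs <- .parse_group(cu, prefixes)
        node <- list(type = "union", left = node, right = rhs)
      }
      parts[[length(parts) + 1L]] <- node
      next
    }
    if (t$type == "WORD" && low == "graph") {
      cur_next(cu)
      gterm <- .pattern_term(cu, prefixes, allow_literal = FALSE)
      body <- .parse_group(cu, prefixes)
      parts[[length(parts) + 1L]] <- list(type = "graph", graph = gterm,
                                          body = body)
      next
    }
    if (t$type == "WORD" && low == "optional") {
      cur_next(cu)
      body <- .parse_group(cu, prefixes)
      parts[[length(parts) + 1L]] <- list(type = "optional", body = body)
      next
    }
    if (t$type == "WORD" && low == "values") {
      cur_next(cu)
      v <- cur_expect(cu, type = "VAR")
      cur_expect(cu, text = "{")
      terms <- character(0)
      repeat {
        tt <- cur_peek(cu)
        if (tt$text == "}") { cur_next(cu); break }
        terms <- c(terms, .read_term(cu, prefixes, allow_literal = TRUE))
      }
      parts[[length(parts) + 1L]] <- list(type = "values",
                                          var = sub("^\\?", "", v$text),
                                          terms = terms)
      next
    }
    if (t$type == "WORD" && low == "service") {
      cur_next(cu)
      if (tolower(cur_peek(cu)$text) == "silent") cur_next(cu)
      ep <- cur_expect(cu, type = "IRIREF")
      body <- .parse_group(cu, prefixes)
      parts[[length(parts) + 1L]] <- list(type = "service",
                                          endpoint = term_str(ep$text),
                                          body = body)
      next
    }
    if (t$type == "WORD" && low %in% c("filter", "bind", "minus")) {
      cur_stop(cu, paste0("unsupported SPARQL construct '", t$text, "'"))
    }
    # triples block with ';' and ',' abbreviations
    subj <- .pattern_term(cu, prefixes, allow_literal = FALSE)
    repeat {
      pred <- .pattern_term(cu, prefixes, allow_literal = FALSE)
      repeat {
        obj <- .pattern_term(cu, prefixes, allow_literal = TRUE)
        parts[[length(parts) + 1L]] <- list(type = "triple", s = subj,
                                            p = pred, o = obj)
        if (cur_peek(cu)$text == ",") { cur_next(cu); next }
        break
      }
      if (cur_peek(cu)$text == ";") {
        cur_next(cu)
        if (cur_peek(cu)$text %in% c(".", "}")) break
        next
      }
      break
    }
    if (cur_peek(cu)$text == ".") cur_next(cu)
  }
  list(type = "group", parts = parts)
}

# ---- solution sequences ----------------------------------------------------

.unit_solution <- function() {
  structure(data.frame(row.names = 1L), names = character(0))
}
.empty_solution <- function(vars = character(0)) {
  .sol_from(stats::setNames(rep(list(character(0)), length(vars)), vars))
}
# build a solution data.frame from a named list of equal-length columns;
# nrow = number of rows even when there are zero variables
.sol_from <- function(cols, nrow_hint = NULL) {
  if (length(cols) == 0L) {
    n <- if (is.null(nrow_hint)) 0L else nrow_hint
    return(structure(data.frame(row.names = seq_len(n)),
                     names = character(0)))
  }
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE,
                optional = TRUE)
}

# SPARQL-compatible join of two solution sequences
.sol_join <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(.empty_solution(union(names(a), names(b))))
  }
  common <- intersect(names(a), names(b))
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  ok <- rep(TRUE, length(ia))
  for (v in common) {
    av <- a[[v]][ia]; bv <- b[[v]][ib]
    ok <- ok & (is.na(av) | is.na(bv) | av == bv)
  }
  ia <- ia[ok]; ib <- ib[ok]
  vars <- union(names(a), names(b))
  cols <- list()
  for (v in vars) {
    av <- if (v %in% names(a)) a[[v]][ia] else rep(NA_character_, length(ia))
    bv <- if (v %in% names(b)) b[[v]][ib] else rep(NA_character_, length(ia))
    cols[[v]] <- ifelse(is.na(av), bv, av)
  }
  .sol_from(cols, nrow_hint = length(ia))
}

# left (OPTIONAL) join: keep unmatched rows of a with NAs for b-only vars
.sol_left_join <- function(a, b) {
  if (nrow(a) == 0L) return(.empty_solution(union(names(a), names(b))))
  if (nrow(b) == 0L) {
    out <- a
    for (v in setdiff(names(b), names(a))) out[[v]] <- NA_character_
    return(out)
  }
  common <- intersect(names(a), names(b))
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  ok <- rep(TRUE, length(ia))
  for (v in common) {
    av <- a[[v]][ia]; bv <- b[[v]][ib]
    ok <- ok & (is.na(av) | is.na(bv) | av == bv)
  }
  ia <- ia[ok]; ib <- ib[ok]
  vars <- union(names(a), names(b))
  cols <- list()
  for (v in vars) {
    av <- if (v %in% names(a)) a[[v]][ia] else rep(NA_character_, length(ia))
    bv <- if (v %in% names(b)) b[[v]][ib] else rep(NA_character_, length(ia))
    cols[[v]] <- ifelse(is.na(av), bv, av)
  }
  out <- .sol_from(cols, nrow_hint = length(ia))
  unmatched <- setdiff(seq_len(nrow(a)), unique(ia))
  if (length(unmatched) > 0L) {
    ecols <- list()
    for (v in vars) {
      ecols[[v]] <- if (v %in% names(a)) a[[v]][unmatched]
                    else rep(NA_character_, length(unmatched))
    }
    out <- rbind(out, .sol_from(ecols, nrow_hint = length(unmatched)))
  }
  out
}

.sol_union <- function(a, b) {
  vars <- union(names(a), names(b))
  for (v in setdiff(vars, names(a))) a[[v]] <- rep(NA_character_, nrow(a))
  for (v in setdiff(vars, names(b))) b[[v]] <- rep(NA_character_, nrow(b))
  rbind(a[vars], b[vars])
}

# ---- evaluation ------------------------------------------------------------

# match one triple pattern against the active graph ("" = default graph,
# NULL means default graph too; a character scalar is an encoded graph IRI)
.eval_triple <- function(node, ds, active) {
  if (is.null(active)) active <- ""
  sel <- ds$g == active
  s <- ds$s[sel]; p <- ds$p[sel]; o <- ds$o[sel]
  keep <- rep(TRUE, length(s))
  if (!is.null(node$s$term)) keep <- keep & s == node$s$term
  if (!is.null(node$p$term)) keep <- keep & p == node$p$term
  if (!is.null(node$o$term)) keep <- keep & o == node$o$term
  s <- s[keep]; p <- p[keep]; o <- o[keep]
  bind <- list()
  if (!is.null(node$s$var)) bind[[node$s$var]] <- s
  if (!is.null(node$p$var)) bind[[node$p$var]] <- p
  if (!is.null(node$o$var)) bind[[node$o$var]] <- o
  # repeated variable in one pattern (e.g. ?x p ?x): enforce equality
  n <- length(s)
  keep2 <- rep(TRUE, n)
  nm <- names(bind)
  if (anyDuplicated(nm)) {
    for (v in unique(nm[duplicated(nm)])) {
      cols <- which(nm == v)
      for (k in cols[-1]) keep2 <- keep2 & bind[[cols[1]]] == bind[[k]]
    }
    bind <- bind[!duplicated(nm)]
    nm <- names(bind)
  }
  if (length(bind) == 0L) {
    if (sum(keep2) > 0L) {
      return(structure(data.frame(row.names = seq_len(sum(keep2))),
                       names = character(0)))
    }
    return(.empty_solution())
  }
  .sol_from(lapply(bind, function(col) col[keep2]))
}

.eval_node <- function(node, ds, active) {
  switch(node$type,
    group = {
      acc <- .unit_solution()
      for (part in node$parts) {
        if (identical(part$type, "optional")) {
          acc <- .sol_left_join(acc, .eval_node(part$body, ds, active))
        } else {
          acc <- .sol_join(acc, .eval_node(part, ds, active))
        }
        if (nrow(acc) == 0L && length(node$parts) > 0L) {
          # keep collecting variable names for a well-shaped empty result
        }
      }
      acc
    },
    triple = .eval_triple(node, ds, active),
    values = .sol_from(stats::setNames(list(node$terms), node$var)),
    union = .sol_union(.eval_node(node$left, ds, active),
                       .eval_node(node$right, ds, active)),
    optional = .sol_left_join(.unit_solution(), .eval_node(node$body, ds, active)),
    graph = {
      graphs <- unique(ds$g[ds$g != ""])
      res <- NULL
      if (!is.null(node$graph$term)) {
        res <- .eval_node(node$body, ds, node$graph$term)
      } else {
        v <- node$graph$var
        for (g in sort(graphs, method = "radix")) {
          r <- .eval_node(node$body, ds, g)
          r <- .sol_join(r, .sol_from(stats::setNames(list(g), v)))
          res <- if (is.null(res)) r else .sol_union(res, r)
        }
        if (is.null(res)) res <- .empty_solution(v)
      }
      res
    },
    service = stop("SERVICE clause for unmapped endpoint <", node$endpoint,
                   ">: rewrite it with rewrite_service() or supply a mapping",
                   call. = FALSE),
    stop("unsupported pattern node: ", node$type, call. = FALSE)
  )
}

# sort key for ORDER BY: unbound first, then by numeric value when the
# column is numeric-literal-valued, else bytewise on the encoded term
.order_solutions <- function(sol, order_by) {
  order_by <- intersect(order_by, names(sol))
  if (length(order_by) == 0L || nrow(sol) <= 1L) return(sol)
  keys <- list()
  for (v in order_by) {
    col <- sol[[v]]
    keys[[length(keys) + 1L]] <- !is.na(col)  # unbound sorts lowest
    num <- term_numeric(col)
    if (any(!is.na(num))) {
      keys[[length(keys) + 1L]] <- ifelse(is.na(num), Inf, num)
      keys[[length(keys) + 1L]] <- ifelse(is.na(col), "", col)
    } else {
      keys[[length(keys) + 1L]] <- ifelse(is.na(col), "", col)
    }
  }
  sol[do.call(order, c(keys, list(method = "radix"))), , drop = FALSE]
}

#' Evaluate a SPARQL SELECT query over a dataset
#'
#' Covers the SPARQL 1.1 fragment used by the canned GlycoCoO queries (basic
#' graph patterns, GRAPH, OPTIONAL, UNION, single-variable VALUES, DISTINCT,
#' `str()` projections, ORDER BY). SERVICE clauses are not contacted: rewrite
#' them first with [rewrite_service()]. Queries lacking declarations for the
#' well-known prefixes rdf/rdfs/xsd get them implicitly, matching how the
#' published query texts rely on rdfs: without declaring it.
#'
#' @param dataset a `glyco_dataset`.
#' @param query SPARQL SELECT text.
#' @return data.frame of decoded result rows (IRIs and literal lexical forms
#'   as strings, `NA` for unbound), one column per projected variable, in
#'   query order. The encoded solution terms are attached as attribute
#'   `encoded`.
#' @export
sparql_select <- function(dataset, query) {
  stopifnot(inherits(dataset, "glyco_dataset"))
  qp <- .parse_sparql(paste(query, collapse = "\n"))
  sol <- .eval_node(qp$where, dataset, NULL)
  sol <- .order_solutions(sol, qp$order_by)

  if (qp$star) {
    items <- lapply(sort(names(sol), method = "radix"),
                    function(v) list(kind = "var", var = v))
  } else {
    items <- qp$items
  }
  out_names <- vapply(items, function(it) {
    if (it$kind == "str") it$alias else it$var
  }, character(1))
  ecols <- list()
  for (i in seq_along(items)) {
    it <- items[[i]]
    col <- if (it$var %in% names(sol)) sol[[it$var]]
           else rep(NA_character_, nrow(sol))
    if (it$kind == "str" && nrow(sol) > 0L) {
      col <- ifelse(is.na(col), NA_character_, lit_string(term_str(col)))
    }
    ecols[[out_names[i]]] <- col
  }
  enc <- .sol_from(ecols, nrow_hint = nrow(sol))
  if (qp$distinct && nrow(enc) > 0L) {
    enc <- enc[!duplicated(enc), , drop = FALSE]
  }
  dec <- enc
  for (v in names(dec)) {
    dec[[v]] <- term_str(as.character(enc[[v]]))
  }
  rownames(dec) <- NULL
  rownames(enc) <- NULL
  attr(dec, "encoded") <- enc
  dec
}

# ---- SERVICE rewriting -----------------------------------------------------

#' Rewrite SERVICE clauses for offline evaluation
#'
#' Replaces each `SERVICE <endpoint> { ... }` block whose endpoint appears in
#' `endpoints` by its body (braces preserved), so a federated query published
#' against live endpoints evaluates against local named-graph copies with
#' zero network access. The body's GRAPH patterns are untouched: local
#' evaluation matches remote evaluation whenever the local graphs equal the
#' remote content.
#'
#' @param query SPARQL query text.
#' @param endpoints character vector of endpoint IRIs that have local copies
#'   (values of a named vector are ignored; names or values may carry graph
#'   hints for documentation).
#' @param passthrough if TRUE, SERVICE clauses for unmapped endpoints are
#'   left in the text (live federation as opt-in); if FALSE (default), an
#'   unmapped endpoint is an error naming the IRI.
#' @return the rewritten query text.
#' @export
#' @examples
#' q <- "select ?s where { SERVICE <http://ex.org/sparql> { ?s ?p ?o } }"
#' cat(rewrite_service(q, "http://ex.org/sparql"))
rewrite_service <- function(query, endpoints, passthrough = FALSE) {
  query <- paste(query, collapse = "\n")
  if (!is.null(names(endpoints)) && any(nzchar(names(endpoints)))) {
    endpoints <- names(endpoints)
  }
  toks <- tokenize_rdf(query)
  # locate SERVICE keywords with their endpoint IRI tokens
  hits <- which(toks$type == "WORD" & tolower(toks$text) == "service")
  if (length(hits) == 0L) return(query)
  offsets <- toks$start
  cut_from <- integer(0); cut_to <- integer(0)
  for (h in hits) {
    j <- h + 1L
    if (j <= nrow(toks) && tolower(toks$text[j]) == "silent") j <- j + 1L
    if (j > nrow(toks) || toks$type[j] != "IRIREF") {
      stop("malformed SERVICE clause (no endpoint IRI)", call. = FALSE)
    }
    ep <- term_str(toks$text[j])
    if (!(ep %in% endpoints)) {
      if (passthrough) next
      stop("no local mapping for SERVICE endpoint <", ep,
           ">; offline evaluation cannot proceed", call. = FALSE)
    }
    # drop 'SERVICE <iri>' (and SILENT), keep the following group braces
    cut_from <- c(cut_from, offsets[h])
    cut_to <- c(cut_to, offsets[j] + nchar(toks$text[j]) - 1L)
  }
  if (length(cut_from) == 0L) return(query)
  keep <- rep(TRUE, nchar(query))
  for (k in seq_along(cut_from)) keep[cut_from[k]:cut_to[k]] <- FALSE
  chars <- strsplit(query, "", fixed = TRUE)[[1]]
  paste(chars[keep], collapse = "")
}
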