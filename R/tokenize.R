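# Single-pass tokenizer shared by the Turtle/TriG/N-Quads reader and the
# SPARQL parser. Alternation order matters: strings and IRIs are matched
# before comments so '#' inside them is not treated as a comment start.
.token_regex <- paste(
  "\"(?:[^\"\\\\\r\n]|\\\\.)*\"",                       # STRING (single line)
  "<[^<>\"{}|^`\\\\[:space:]]*>",                       # IRIREF
  "#[^\r\n]*",                                          # COMMENT
  "\\^\\^",                                             # datatype marker
  "@[A-Za-z][A-Za-z0-9-]*",                             # langtag / @prefix
  "\\?[A-Za-z_][A-Za-z0-9_]*",                          # SPARQL variable
  "_:[A-Za-z0-9_]+",                                    # blank node label
  paste0("(?:[A-Za-z][A-Za-z0-9_.-]*)?:",               # PNAME
         "(?:[A-Za-z0-9_](?:[A-Za-z0-9_.%-]*[A-Za-z0-9_%-])?)?"),
  "[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",      # number
  "[A-Za-z][A-Za-z0-9_-]*",                             # bare word / keyword
  "[.;,{}()*]",                                         # punctuation
  sep = "|")

# returns data.frame(text, type, line, col); errors on any non-whitespace
# character not covered by a token
tokenize_rdf <- function(text) {
  text <- paste(text, collapse = "\n")
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (length(starts) == 0L || starts[1] == -1L) {
    bad <- regexpr("[^ \t\r\n\ufeff]", text)
    if (bad > 0L) {
      stop(sprintf("syntax error: unexpected character '%s' at position %d",
                   substr(text, bad, bad), bad), call. = FALSE)
    }
    return(data.frame(text = character(0), type = character(0),
                      line = integer(0), col = integer(0),
                      start = integer(0), stringsAsFactors = FALSE))
  }
  toks <- substring(text, starts, starts + lens - 1L)

  # coverage check: everything outside tokens must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) covered[starts[i]:(starts[i] + lens[i] - 1L)] <- TRUE
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  stray <- which(!covered & !(chars %in% c(" ", "\t", "\r", "\n", "\ufeff")))
  line_of <- function(pos) {
    prior <- substr(text, 1L, pos - 1L)
    nl <- gregexpr("\n", prior, fixed = TRUE)[[1]]
    nnl <- if (nl[1] == -1L) 0L else length(nl)
    c(line = nnl + 1L, col = pos - (if (nnl == 0L) 0L else max(nl)))
  }
  if (length(stray) > 0L) {
    lc <- line_of(stray[1])
    stop(sprintf("syntax error: unexpected character '%s' at line %d, column %d",
                 chars[stray[1]], lc["line"], lc["col"]), call. = FALSE)
  }

  type <- character(length(toks))
  first <- substr(toks, 1L, 1L)
  type[first == "\""] <- "STRING"
  type[first == "<"] <- "IRIREF"
  type[first == "#"] <- "COMMENT"
  type[toks == "^^"] <- "DTYPE"
  type[first == "@"] <- "AT"
  type[first == "?"] <- "VAR"
  type[startsWith(toks, "_:")] <- "BLANK"
  type[type == "" & grepl("^[+-]?[0-9]", toks)] <- "NUMBER"
  type[type == "" & grepl(":", toks, fixed = TRUE)] <- "PNAME"
  type[type == "" & grepl("^[A-Za-z]", toks)] <- "WORD"
  type[type == ""] <- "PUNCT"

  keep <- type != "COMMENT"
  starts <- starts[keep]; toks <- toks[keep]; type <- type[keep]

  nl_pos <- gregexpr("\n", text, fixed = TRUE)[[1]]
  if (nl_pos[1] == -1L) nl_pos <- integer(0)
  line <- findInterval(starts, nl_pos) + 1L
  col <- starts - ifelse(line > 1L, nl_pos[line - 1L], 0L)

  data.frame(text = toks, type = type, line = line, col = col,
             start = starts, stringsAsFactors = FALSE)
}

# token-stream cursor used by both parsers
new_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tok <- tokens
  env$i <- 1L
  env
}
cur_eof <- function(cu) cu$i > nrow(cu$tok)
cur_peek <- function(cu, ahead = 0L) {
  j <- cu$i + ahead
  if (j > nrow(cu$tok)) list(text = "", type = "EOF", line = NA, col = NA)
  else as.list(cu$tok[j, ])
}
cur_next <- function(cu) {
  t <- cur_peek(cu)
  cu$i <- cu$i + 1L
  t
}
cur_expect <- function(cu, text = NULL, type = NULL) {
  t <- cur_next(cu)
  ok <- TRUE
  if (!is.null(text) && !identical(tolower(t$text), tolower(text))) ok <- FALSE
  if (!is.null(type) && !identical(t$type, type)) ok <- FALSE
  if (!ok) {
    stop(sprintf("syntax error: expected %s but found '%s' at line %s, column %s",
                 if (!is.null(text)) sQuote(text) else type,
                 t$text, t$line, t$col), call. = FALSE)
  }
  t
}
cur_stop <- function(cu, msg) {
  t <- cur_peek(cu)
  stop(sprintf("syntax error: %s at line %s, column %s (near '%s')",
               msg, t$line, t$col, t$text), call. = FALSE)
}
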