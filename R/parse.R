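# Recursive-descent parser for the BEL subset. Hand-written on purpose: the
# grammar is small (15 functions, 9 relations, one statement-nesting level)
# and precise character offsets in error messages matter for curation.

normalize_quotes <- function(x) {
  # PDF-derived text carries smart quotes and dashes; normalize before parsing
  x <- gsub("‘|’|ʼ", "'", x)
  x <- gsub("“|”", "\"", x)
  x <- gsub("–|—|−", "-", x)
  gsub(" ", " ", x)
}

parse_error <- function(msg, offset) {
  abort(sprintf("%s at offset %d", msg, offset),
        class = "bel_parse_error", offset = offset)
}

new_cursor <- function(text) {
  env <- new.env(parent = emptyenv())
  env$s <- strsplit(text, "", fixed = TRUE)[[1L]]
  env$n <- length(env$s)
  env$i <- 1L  # 1-based index; reported offsets are 0-based
  env
}

cur_off <- function(p) p$i - 1L
cur_eof <- function(p) p$i > p$n
cur_peek <- function(p) if (cur_eof(p)) "" else p$s[p$i]
cur_skip_ws <- function(p) {
  while (!cur_eof(p) && grepl("^[ \t\r\n]$", p$s[p$i])) p$i <- p$i + 1L
  invisible(p)
}
cur_expect <- function(p, ch) {
  if (cur_peek(p) != ch) {
    parse_error(sprintf("expected '%s'", ch), cur_off(p))
  }
  p$i <- p$i + 1L
}

cur_ident <- function(p) {
  # identifier: word characters (function names, namespace keywords)
  start <- p$i
  while (!cur_eof(p) && grepl("^[A-Za-z0-9_]$", p$s[p$i])) p$i <- p$i + 1L
  if (p$i == start) parse_error("expected identifier", cur_off(p))
  paste(p$s[start:(p$i - 1L)], collapse = "")
}

cur_value <- function(p) {
  # namespace value: quoted string or bare token
  if (cur_peek(p) == "'") {
    p$i <- p$i + 1L
    start <- p$i
    while (!cur_eof(p) && p$s[p$i] != "'") p$i <- p$i + 1L
    if (cur_eof(p)) parse_error("unterminated quoted value", cur_off(p))
    val <- if (p$i > start) paste(p$s[start:(p$i - 1L)], collapse = "") else ""
    p$i <- p$i + 1L
    if (!nzchar(val)) parse_error("empty namespace value", cur_off(p) - 2L)
    return(val)
  }
  start <- p$i
  while (!cur_eof(p) && grepl("^[A-Za-z0-9_.-]$", p$s[p$i])) p$i <- p$i + 1L
  if (p$i == start) parse_error("empty namespace value", cur_off(p))
  paste(p$s[start:(p$i - 1L)], collapse = "")
}

p_nsv <- function(p) {
  ns <- cur_ident(p)
  cur_skip_ws(p)
  cur_expect(p, ":")
  cur_skip_ws(p)
  bel_nsv(ns, cur_value(p))
}

p_term <- function(p) {
  at <- cur_off(p)
  id <- cur_ident(p)
  short <- fn_short(id)
  if (is.na(short)) parse_error(sprintf("unknown function keyword '%s'", id), at)
  cur_skip_ws(p)
  cur_expect(p, "(")
  args <- list()
  repeat {
    cur_skip_ws(p)
    if (cur_peek(p) == ")" || cur_eof(p)) {
      parse_error("empty argument", cur_off(p))
    }
    # lookahead: identifier followed by '(' is a nested term, else nsv
    save <- p$i
    ok_term <- FALSE
    id2 <- tryCatch(cur_ident(p), error = function(e) NULL)
    if (!is.null(id2)) {
      cur_skip_ws(p)
      if (cur_peek(p) == "(" && !is.na(fn_short(id2))) ok_term <- TRUE
    }
    p$i <- save
    args[[length(args) + 1L]] <- if (ok_term) p_term(p) else p_nsv(p)
    cur_skip_ws(p)
    if (cur_peek(p) == ",") { p$i <- p$i + 1L; next }
    break
  }
  cur_expect(p, ")")
  bel_term(short, args)
}

p_relation <- function(p, required = TRUE) {
  cur_skip_ws(p)
  two <- if (p$i + 1L <= p$n) paste(p$s[p$i:(p$i + 1L)], collapse = "") else ""
  i <- match(two, .bel_relations$symbol)
  if (!is.na(i)) {
    p$i <- p$i + 2L
    return(.bel_relations$name[i])
  }
  if (grepl("^[A-Za-z]$", cur_peek(p))) {
    save <- p$i
    id <- cur_ident(p)
    if (id %in% .bel_relations$name) return(id)
    p$i <- save
  }
  if (required) parse_error("unknown relation token", cur_off(p))
  NULL
}

#' Parse a BEL term expression
#'
#' Whitespace-insensitive; single-quoted values are preserved verbatim without
#' the quotes; smart quotes are normalized to ASCII before parsing.
#'
#' @param text A single BEL term expression, e.g.
#'   `"sec(a(CHEBI:'20-HETE'))"`.
#' @return A [bel_term()] object.
#' @export
#' @examples
#' parse_term("bp(GOBP:angiogenesis)")
#' parse_term("sec(a(CHEBI:'20-HETE'))")
parse_term <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  p <- new_cursor(normalize_quotes(text))
  cur_skip_ws(p)
  t <- p_term(p)
  cur_skip_ws(p)
  if (!cur_eof(p)) parse_error("trailing input after term", cur_off(p))
  t
}

#' Parse a BEL statement, possibly a fragment
#'
#' Accepts complete statements (`"A -> B"`), statements with a parenthesized
#' nested object (`"A -> (B -> C)"`, one nesting level), and the two fragment
#' forms produced by automated extraction: `"A ->"` (subject--relation) and
#' `"-> B"` (relation--object).
#'
#' @param text A single BEL statement in BEL Script syntax.
#' @return A [bel_statement()] object.
#' @export
#' @examples
#' parse_statement("p(HGNC:CYP4A11) -> bp(GOBP:angiogenesis)")
#' parse_statement("-> bp(GOBP:angiogenesis)")
parse_statement <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  p <- new_cursor(normalize_quotes(text))
  cur_skip_ws(p)
  if (cur_eof(p)) parse_error("empty statement", 0L)

  rel <- p_relation(p, required = FALSE)
  if (!is.null(rel)) {
    # relation-object fragment
    cur_skip_ws(p)
    obj <- p_statement_object(p)
    cur_skip_ws(p)
    if (!cur_eof(p)) parse_error("trailing input after statement", cur_off(p))
    return(bel_statement(NULL, rel, obj))
  }

  subj <- p_term(p)
  cur_skip_ws(p)
  if (cur_eof(p)) parse_error("expected relation after subject", cur_off(p))
  rel <- p_relation(p, required = TRUE)
  cur_skip_ws(p)
  if (cur_eof(p)) {
    return(bel_statement(subj, rel, NULL))  # subject-relation fragment
  }
  obj <- p_statement_object(p)
  cur_skip_ws(p)
  if (!cur_eof(p)) parse_error("trailing input after statement", cur_off(p))
  bel_statement(subj, rel, obj)
}

p_statement_object <- function(p) {
  if (cur_peek(p) == "(") {
    # parenthesized nested statement object
    at <- cur_off(p)
    p$i <- p$i + 1L
    cur_skip_ws(p)
    subj <- p_term(p)
    rel <- p_relation(p, required = TRUE)
    cur_skip_ws(p)
    if (cur_peek(p) == "(") {
      parse_error("nested statement object may not itself nest", cur_off(p))
    }
    obj <- p_term(p)
    cur_skip_ws(p)
    if (cur_peek(p) != ")") parse_error("expected ')'", cur_off(p))
    p$i <- p$i + 1L
    inner <- bel_statement(subj, rel, obj)
    return(inner)
  }
  p_term(p)
}
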