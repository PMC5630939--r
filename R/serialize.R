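# Canonical serialization: short function names, upper-case namespace
# keywords, values quoted only when they contain characters outside
# [A-Za-z0-9_-]. parse(serialize(x)) is the structural identity.

serialize_nsv <- function(x) {
  v <- x$value
  if (grepl("[^A-Za-z0-9_-]", v)) v <- paste0("'", v, "'")
  paste0(x$namespace, ":", v)
}

#' Serialize a BEL term to canonical text
#'
#' @param x A [bel_term()].
#' @return A single string; [parse_term()] of the result reproduces `x`.
#' @export
#' @examples
#' serialize_term(parse_term("cellSecretion( a( CHEBI : '20-HETE' ) )"))
serialize_term <- function(x) {
  stopifnot(inherits(x, "bel_term"))
  args <- vapply(x$args, function(a) {
    if (inherits(a, "bel_term")) serialize_term(a) else serialize_nsv(a)
  }, character(1L))
  paste0(x$fn, "(", paste(args, collapse = ", "), ")")
}

relation_token <- function(name) {
  i <- match(name, .bel_relations$name)
  sym <- .bel_relations$symbol[i]
  if (is.na(sym)) name else sym
}

#' Serialize a BEL statement to canonical text
#'
#' Deterministic canonical form: operator symbols where they exist
#' (`->`, `-|`, `=>`, `=|`, `--`), word relations otherwise; nested statement
#' objects parenthesized; fragments keep their dangling side.
#'
#' @param x A [bel_statement()].
#' @return A single string; [parse_statement()] of the result reproduces `x`.
#' @export
#' @examples
#' serialize_statement(parse_statement("p(HGNC:CYP4A11)->bp(GOBP:angiogenesis)"))
serialize_statement <- function(x) {
  stopifnot(inherits(x, "bel_statement"))
  rel <- relation_token(x$relation)
  obj <- if (is.null(x$object)) NULL
    else if (inherits(x$object, "bel_statement"))
      paste0("(", serialize_statement(x$object), ")")
    else serialize_term(x$object)
  subj <- if (is.null(x$subject)) NULL else serialize_term(x$subject)
  paste(c(subj, rel, obj), collapse = " ")
}
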