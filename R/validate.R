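# Syntax/structure validator. Violations are data (a tibble), not errors:
# the curation loop surfaces them to the user and refuses edits that would
# introduce any.

violation <- function(rule, expression, message) {
  tibble(rule = rule, expression = expression, message = message)
}

no_violations <- function() {
  tibble(rule = character(), expression = character(), message = character())
}

term_depth <- function(t) {
  if (!inherits(t, "bel_term")) return(0L)
  inner <- vapply(t$args, term_depth, integer(1L))
  1L + if (length(inner)) max(inner) else 0L
}

validate_term <- function(t) {
  v <- no_violations()
  expr <- serialize_term(t)
  cls <- fn_class(t$fn)
  is_term <- vapply(t$args, inherits, TRUE, what = "bel_term")

  if (cls == "simple") {
    if (length(t$args) != 1L || any(is_term)) {
      v <- bind_rows(v, violation(
        "arity_simple", expr,
        sprintf("%s() takes exactly one namespace value", t$fn)))
    }
  } else if (cls == "group") {
    ok <- (length(t$args) == 1L && !is_term[1L]) ||
      (length(t$args) >= 2L && all(is_term))
    if (!ok) {
      v <- bind_rows(v, violation(
        "arity_group", expr,
        sprintf("%s() takes one namespace value or >= 2 member terms", t$fn)))
    }
  } else if (cls == "wrapper") {
    if (length(t$args) != 1L || !is_term[1L]) {
      v <- bind_rows(v, violation(
        "arity_wrapper", expr,
        sprintf("%s() takes exactly one inner term", t$fn)))
    } else if (!t$args[[1L]]$fn %in% .abundance_functions) {
      v <- bind_rows(v, violation(
        "wrapper_inner_class", expr,
        sprintf("%s() requires an abundance-class inner term, got %s()",
                t$fn, t$args[[1L]]$fn)))
    }
  }
  if (term_depth(t) > 2L) {
    v <- bind_rows(v, violation(
      "term_depth", expr, "term nesting depth exceeds 2"))
  }
  for (a in t$args) if (inherits(a, "bel_term")) {
    v <- bind_rows(v, validate_term(a))
  }
  v
}

term_namespaces <- function(t) {
  out <- character()
  for (a in t$args) {
    out <- c(out, if (inherits(a, "bel_term")) term_namespaces(a)
             else a$namespace)
  }
  unique(out)
}

statement_namespaces <- function(s) {
  out <- character()
  if (!is.null(s$subject)) out <- c(out, term_namespaces(s$subject))
  if (!is.null(s$object)) {
    out <- c(out, if (inherits(s$object, "bel_statement"))
      statement_namespaces(s$object) else term_namespaces(s$object))
  }
  unique(out)
}

#' Validate a BEL statement
#'
#' Checks term arity and argument classes, term nesting depth (max 2),
#' statement nesting depth (a nested object statement must be complete and
#' may not itself nest) and, when a document context is supplied, that every
#' namespace used is declared in it.
#'
#' @param s A [bel_statement()].
#' @param doc Optional [bel_document()] providing declared namespaces.
#' @return A tibble of violations with columns `rule`, `expression`,
#'   `message`; zero rows when the statement is valid.
#' @export
#' @examples
#' validate_statement(parse_statement("p(HGNC:CYP4A11) -> bp(GOBP:angiogenesis)"))
validate_statement <- function(s, doc = NULL) {
  stopifnot(inherits(s, "bel_statement"))
  v <- no_violations()
  if (!is.null(s$subject)) v <- bind_rows(v, validate_term(s$subject))
  if (!is.null(s$object)) {
    if (inherits(s$object, "bel_statement")) {
      inner <- s$object
      if (inner$fragment_kind != "complete") {
        v <- bind_rows(v, violation(
          "nested_fragment", serialize_statement(s),
          "nested statement object must be complete"))
      }
      if (!is.null(inner$object) && inherits(inner$object, "bel_statement")) {
        v <- bind_rows(v, violation(
          "statement_depth", serialize_statement(s),
          "nested statement object may not itself nest"))
      }
      if (!is.null(inner$subject)) v <- bind_rows(v, validate_term(inner$subject))
      if (!is.null(inner$object) && inherits(inner$object, "bel_term")) {
        v <- bind_rows(v, validate_term(inner$object))
      }
    } else {
      v <- bind_rows(v, validate_term(s$object))
    }
  }
  if (!is.null(doc)) {
    used <- statement_namespaces(s)
    undeclared <- setdiff(used, names(doc$namespaces))
    for (ns in undeclared) {
      v <- bind_rows(v, violation(
        "undeclared_namespace", serialize_statement(s),
        sprintf("namespace %s is not declared in the document", ns)))
    }
  }
  v
}

#' Validate a whole BEL document
#'
#' Runs [validate_statement()] on every statement against the document's
#' declarations and checks that every annotation key used in a block is
#' defined.
#'
#' @param doc A [bel_document()].
#' @return A tibble of violations (zero rows when valid), with a `block`
#'   column locating each violation.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "bel_document"))
  out <- list()
  for (b in seq_along(doc$blocks)) {
    blk <- doc$blocks[[b]]
    bad_keys <- setdiff(names(blk$annotations), names(doc$annotations))
    for (k in bad_keys) {
      out[[length(out) + 1L]] <- cbind(
        violation("undefined_annotation", k,
                  sprintf("annotation key '%s' is not defined", k)),
        block = b)
    }
    for (s in blk$statements) {
      v <- validate_statement(s, doc)
      if (nrow(v)) out[[length(out) + 1L]] <- cbind(v, block = b)
    }
  }
  if (!length(out)) return(cbind(no_violations(), block = integer()))
  as_tibble(bind_rows(out))
}
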