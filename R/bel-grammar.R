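# BEL language inventory: the 15 term functions and 9 relationship types the
# curation workflow uses, with the structural classes the validator enforces.

# function classes:
#   simple  - take exactly one namespace value (a, p, r, g, bp, path)
#   group   - complex/composite: one namespace value OR >= 2 member terms
#   wrapper - activities, deg, sec: exactly one inner term that must be a
#             true abundance (a, p, r, g, complex, composite)
.bel_functions <- data.frame(
  long = c(
    "abundance", "proteinAbundance", "rnaAbundance", "geneAbundance",
    "complexAbundance", "compositeAbundance", "molecularActivity",
    "peptidaseActivity", "kinaseActivity", "catalyticActivity",
    "transcriptionalActivity", "degradation", "cellSecretion",
    "biologicalProcess", "pathology"
  ),
  short = c(
    "a", "p", "r", "g", "complex", "composite", "act", "pep", "kin", "cat",
    "tscript", "deg", "sec", "bp", "path"
  ),
  class = c(
    "simple", "simple", "simple", "simple", "group", "group", "wrapper",
    "wrapper", "wrapper", "wrapper", "wrapper", "wrapper", "wrapper",
    "simple", "simple"
  ),
  stringsAsFactors = FALSE
)

# functions whose terms denote a molecular abundance; wrappers may only be
# applied to these (a process such as bp() cannot have kinase activity)
.abundance_functions <- c("a", "p", "r", "g", "complex", "composite")

.bel_relations <- data.frame(
  name = c(
    "increases", "decreases", "directlyIncreases", "directlyDecreases",
    "causesNoChange", "association", "hasComponent", "transcribedTo",
    "translatedTo"
  ),
  symbol = c("->", "-|", "=>", "=|", NA, "--", NA, NA, NA),
  causal = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' BEL term functions recognized by the parser
#'
#' The grammar covers the 15 term functions observed in curated
#' plaque-destabilization networks: six single-argument abundance/process
#' functions, two grouping functions and seven activity/processing wrappers.
#'
#' @return A tibble with columns `long`, `short` and `class`
#'   (`simple`, `group` or `wrapper`).
#' @export
#' @examples
#' bel_functions()
bel_functions <- function() tibble::as_tibble(.bel_functions)

#' BEL relationship types
#'
#' Causal relationships (`increases`, `decreases`, `directlyIncreases`,
#' `directlyDecreases`, `causesNoChange`) carry cause-and-effect semantics;
#' the remaining relationships are non-causal and link alternative forms of
#' one entity (gene to RNA to protein, complex to component) or correlations.
#'
#' @return A tibble with columns `name`, `symbol` (NA when the relation has
#'   no operator form) and `causal`.
#' @export
#' @examples
#' bel_relations()
bel_relations <- function() tibble::as_tibble(.bel_relations)

relation_is_causal <- function(name) {
  .bel_relations$causal[match(name, .bel_relations$name)]
}

fn_short <- function(name) {
  i <- match(name, .bel_functions$long)
  j <- match(name, .bel_functions$short)
  out <- ifelse(is.na(i), .bel_functions$short[j], .bel_functions$short[i])
  out
}

fn_class <- function(short) {
  .bel_functions$class[match(short, .bel_functions$short)]
}

#' Construct a namespace value
#'
#' @param namespace Namespace keyword (e.g. `"HGNC"`, `"CHEBI"`, `"GOBP"`).
#'   Case-insensitive on input; stored upper-case.
#' @param value Entity identifier within the namespace; must be non-empty.
#' @return An object of class `bel_nsv`.
#' @export
#' @examples
#' bel_nsv("HGNC", "CYP4A11")
bel_nsv <- function(namespace, value) {
  stopifnot(is.character(namespace), length(namespace) == 1L,
            is.character(value), length(value) == 1L)
  if (!nzchar(value)) abort("namespace value must be non-empty",
                            class = "bel_parse_error")
  structure(list(namespace = toupper(namespace), value = value),
            class = "bel_nsv")
}

#' Construct a BEL term
#'
#' Terms are recursive: a function applied to namespace values and/or other
#' terms, e.g. `sec(a(CHEBI:'20-HETE'))`. Structural constraints (arity,
#' wrapper argument class, nesting depth) are checked by
#' [validate_statement()], not at construction.
#'
#' @param fn Function name, long or short form (canonicalized to short).
#' @param ... Arguments: `bel_nsv` or `bel_term` objects.
#' @return An object of class `bel_term`.
#' @export
#' @examples
#' bel_term("p", bel_nsv("HGNC", "CYP4A11"))
bel_term <- function(fn, ...) {
  short <- fn_short(fn)
  if (is.na(short)) {
    abort(paste0("unknown BEL function: ", fn), class = "bel_parse_error")
  }
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) &&
      !inherits(args[[1L]], c("bel_nsv", "bel_term"))) {
    args <- args[[1L]]
  }
  ok <- vapply(args, function(a) inherits(a, c("bel_nsv", "bel_term")), TRUE)
  if (!all(ok)) abort("term arguments must be bel_nsv or bel_term objects")
  structure(list(fn = short, args = args), class = "bel_term")
}

#' Construct a BEL statement
#'
#' A statement is subject--relationship--object. Fragments (subject+relation
#' or relation+object) arise from automated extraction when one participant
#' could not be grounded and await curation assembly.
#'
#' @param subject A `bel_term`, or `NULL` for a relation--object fragment.
#' @param relation Relationship name (e.g. `"increases"`) or operator symbol
#'   (e.g. `"->"`).
#' @param object A `bel_term`, a complete `bel_statement` (one nesting level),
#'   or `NULL` for a subject--relation fragment.
#' @return An object of class `bel_statement` with a `fragment_kind` field:
#'   `"complete"`, `"subject_relation"` or `"relation_object"`.
#' @export
#' @examples
#' bel_statement(
#'   bel_term("p", bel_nsv("HGNC", "CYP4A11")), "increases",
#'   bel_term("bp", bel_nsv("GOBP", "angiogenesis"))
#' )
bel_statement <- function(subject = NULL, relation, object = NULL) {
  rel <- relation
  i <- match(rel, .bel_relations$symbol)
  if (!is.na(i)) rel <- .bel_relations$name[i]
  if (!rel %in% .bel_relations$name) {
    abort(paste0("unknown BEL relation: ", relation),
          class = "bel_parse_error")
  }
  if (is.null(subject) && is.null(object)) {
    abort("a statement needs at least a subject or an object")
  }
  kind <- if (is.null(object)) "subject_relation"
          else if (is.null(subject)) "relation_object"
          else "complete"
  structure(
    list(subject = subject, relation = rel, object = object,
         fragment_kind = kind),
    class = "bel_statement"
  )
}

#' @export
print.bel_nsv <- function(x, ...) {
  cat("<bel_nsv> ", serialize_nsv(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_term <- function(x, ...) {
  cat("<bel_term> ", serialize_term(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement", if (x$fragment_kind != "complete")
    paste0("/", x$fragment_kind), "> ", serialize_statement(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bel_term <- function(x, ...) serialize_term(x)

#' @export
format.bel_statement <- function(x, ...) serialize_statement(x)
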