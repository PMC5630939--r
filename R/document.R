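# BEL document container: header, namespace declarations, annotation
# definitions, and evidence-scoped blocks of statements. The four standard
# context dimensions (Species, Tissue, Cell, Disease) are pre-defined;
# further keys require an explicit definition, mirroring document validation
# in the curation workflow.

standard_annotation_keys <- c("Species", "Tissue", "Cell", "Disease")

#' Construct an evidence record
#'
#' Evidence is the source sentence supporting a statement, with its PubMed
#' identifier, the article section it came from and, when known, its 0-based
#' half-open character span in the cleaned source passage.
#'
#' @param text The evidence sentence.
#' @param pmid PubMed identifier as a string.
#' @param section One of `"abstract"`, `"methods"`, `"results"`.
#' @param span Integer vector `c(start, end)` (0-based, half-open) into the
#'   source passage, or `NULL` when the passage is not available.
#' @return An object of class `bel_evidence`.
#' @export
bel_evidence <- function(text, pmid = NA_character_,
                         section = NA_character_, span = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!is.null(span)) {
    span <- as.integer(span)
    stopifnot(length(span) == 2L, span[2L] > span[1L], span[1L] >= 0L)
  }
  structure(list(text = text, pmid = as.character(pmid),
                 section = as.character(section), span = span),
            class = "bel_evidence")
}

#' Construct an evidence block
#'
#' @param evidence A [bel_evidence()].
#' @param annotations Named list of annotation key/value strings
#'   (e.g. `list(Species = "10090")`).
#' @param statements List of [bel_statement()] objects.
#' @return An object of class `bel_block`.
#' @export
bel_block <- function(evidence, annotations = list(), statements = list()) {
  stopifnot(inherits(evidence, "bel_evidence"))
  if (inherits(statements, "bel_statement")) statements <- list(statements)
  structure(list(evidence = evidence,
                 annotations = annotations,
                 statements = statements),
            class = "bel_block")
}

#' Construct a BEL document
#'
#' @param name,description,version Header fields.
#' @param namespaces Named character vector mapping namespace keywords to
#'   resource URLs (use `"-"` when no URL applies).
#' @param annotations Named character vector of annotation definitions
#'   (key -> match pattern). The four standard keys Species/Tissue/Cell/
#'   Disease are always defined.
#' @param blocks List of [bel_block()] objects.
#' @return An object of class `bel_document`.
#' @export
#' @examples
#' doc <- bel_document(
#'   name = "example", namespaces = c(HGNC = "-", GOBP = "-"),
#'   blocks = list(bel_block(
#'     bel_evidence("CYP4A11 increased angiogenesis.", pmid = "21120482",
#'                  section = "results"),
#'     statements = list(parse_statement("p(HGNC:CYP4A11) -> bp(GOBP:angiogenesis)"))
#'   ))
#' )
#' validate_document(doc)
bel_document <- function(name = "untitled", description = "", version = "1.0",
                         namespaces = character(), annotations = character(),
                         blocks = list()) {
  std <- stats::setNames(rep(".*", length(standard_annotation_keys)),
                         standard_annotation_keys)
  ann <- c(std[setdiff(standard_annotation_keys, names(annotations))],
           annotations)
  if (length(namespaces)) names(namespaces) <- toupper(names(namespaces))
  structure(
    list(header = list(name = name, description = description,
                       version = version),
         namespaces = namespaces, annotations = ann, blocks = blocks),
    class = "bel_document"
  )
}

#' @export
print.bel_document <- function(x, ...) {
  n_stmt <- sum(vapply(x$blocks, function(b) length(b$statements), 1L))
  cat("<bel_document> ", x$header$name, " (v", x$header$version, ")\n",
      "  namespaces:  ", paste(names(x$namespaces), collapse = ", "), "\n",
      "  blocks:      ", length(x$blocks), "\n",
      "  statements:  ", n_stmt, "\n", sep = "")
  invisible(x)
}

document_statements <- function(doc) {
  # flat view with 1-based statement indices in document order
  out <- list()
  idx <- 0L
  for (b in seq_along(doc$blocks)) {
    for (s in doc$blocks[[b]]$statements) {
      idx <- idx + 1L
      out[[idx]] <- list(index = idx, block = b, statement = s)
    }
  }
  out
}

#' Tabulate the statements of a document
#'
#' @param doc A [bel_document()].
#' @return A tibble with one row per statement: `index`, `block`, `pmid`,
#'   `fragment_kind`, `relation`, `text` (canonical serialization).
#' @export
document_statement_table <- function(doc) {
  rows <- document_statements(doc)
  tibble(
    index = vapply(rows, function(r) r$index, 1L),
    block = vapply(rows, function(r) r$block, 1L),
    pmid = vapply(rows, function(r) doc$blocks[[r$block]]$evidence$pmid,
                  character(1L)),
    fragment_kind = vapply(rows, function(r) r$statement$fragment_kind,
                           character(1L)),
    relation = vapply(rows, function(r) r$statement$relation, character(1L)),
    text = vapply(rows, function(r) serialize_statement(r$statement),
                  character(1L))
  )
}
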