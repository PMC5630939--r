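# Event -> BEL conversion, document building with evidence/context
# annotations, JSON sidecar (entity text locations + alternative namespace
# candidates, i.e. the machine-only companion to the XBEL), and programmatic
# curation edits with automatic re-validation.

.default_class_map <- c(
  gene_protein = "p", chemical = "a", process = "bp",
  complex = "complex", family = "p"
)

mention_to_term <- function(namespace, id, bel_class,
                            class_map = .default_class_map) {
  fn <- unname(class_map[bel_class])
  if (length(fn) != 1L || is.null(fn) || is.na(fn)) {
    abort(sprintf("no BEL function mapping for entity class '%s' (%s:%s)",
                  bel_class, namespace, id),
          class = "bel_conversion_error")
  }
  bel_term(fn, bel_nsv(namespace, id))
}

#' Convert a regulation event to a BEL statement
#'
#' Positive_regulation maps to `increases`, Negative_regulation to
#' `decreases` (the indirect forms: automated extraction cannot establish
#' directness), No_regulation to `causesNoChange`. The entity class selects
#' the term function (gene_protein -> p, chemical -> a, process -> bp,
#' complex -> complex, family -> p). An event without a cause converts to a
#' relation--object fragment awaiting curation.
#'
#' @param event A one-row event tibble from [extract_events()].
#' @param class_map Named character vector entity class -> BEL function
#'   short name.
#' @return A [bel_statement()].
#' @export
event_to_statement <- function(event, class_map = .default_class_map) {
  stopifnot(nrow(event) == 1L)
  rel <- switch(event$type,
                Positive_regulation = "increases",
                Negative_regulation = "decreases",
                No_regulation = "causesNoChange",
                abort(paste0("unknown event type: ", event$type)))
  theme <- mention_to_term(event$theme_namespace, event$theme_id,
                           event$theme_class, class_map)
  if (is.na(event$cause_id)) {
    return(bel_statement(NULL, rel, theme))
  }
  cause <- mention_to_term(event$cause_namespace, event$cause_id,
                           event$cause_class, class_map)
  bel_statement(cause, rel, theme)
}

#' Run NER and event extraction over a segmented corpus
#'
#' @param passages A segmented passage tibble ([segment_sentences()]).
#' @param dictionaries Dictionaries in priority order (see [ner()]).
#' @param triggers,negation Passed to [extract_events()].
#' @return A sentence-level tibble: `pmid`, `section`, `sentence_id`,
#'   `start`, `end`, `sentence`, and list-columns `mentions`, `events`.
#' @export
extract_corpus <- function(passages, dictionaries,
                           triggers = default_trigger_lexicon(),
                           negation = "drop") {
  rows <- list()
  for (i in seq_len(nrow(passages))) {
    sent <- passages$sentences[[i]]
    if (is.null(sent) || nrow(sent) == 0L) next
    for (j in seq_len(nrow(sent))) {
      men <- ner(sent$text[j], dictionaries)
      ev <- extract_events(sent$text[j], men, triggers, negation)
      rows[[length(rows) + 1L]] <- tibble(
        pmid = passages$pmid[i], section = passages$section[i],
        sentence_id = sent$sentence_id[j], start = sent$start[j],
        end = sent$end[j], sentence = sent$text[j],
        mentions = list(men), events = list(ev))
    }
  }
  if (!length(rows)) {
    return(tibble(pmid = character(), section = character(),
                  sentence_id = integer(), start = integer(),
                  end = integer(), sentence = character(),
                  mentions = list(), events = list()))
  }
  bind_rows(rows)
}

#' Convert extracted events into statements with evidence links
#'
#' @param extraction Sentence-level tibble from [extract_corpus()].
#' @param class_map See [event_to_statement()].
#' @return A statement-level tibble: one row per converted statement with
#'   its evidence sentence, spans and the mentions that produced it
#'   (`statement` and `mentions` are list-columns).
#' @export
events_to_statements <- function(extraction,
                                 class_map = .default_class_map) {
  rows <- list()
  for (i in seq_len(nrow(extraction))) {
    evts <- extraction$events[[i]]
    if (is.null(evts) || nrow(evts) == 0L) next
    for (j in seq_len(nrow(evts))) {
      ev <- evts[j, , drop = FALSE]
      s <- event_to_statement(ev, class_map)
      men <- ev[, c("cause_start", "cause_end", "cause_text",
                    "cause_namespace", "cause_id",
                    "theme_start", "theme_end", "theme_text",
                    "theme_namespace", "theme_id")]
      rows[[length(rows) + 1L]] <- tibble(
        pmid = extraction$pmid[i], section = extraction$section[i],
        sentence_id = extraction$sentence_id[i],
        start = extraction$start[i], end = extraction$end[i],
        sentence = extraction$sentence[i],
        statement = list(s), mentions = list(men))
    }
  }
  if (!length(rows)) {
    return(tibble(pmid = character(), section = character(),
                  sentence_id = integer(), start = integer(),
                  end = integer(), sentence = character(),
                  statement = list(), mentions = list()))
  }
  bind_rows(rows)
}

#' Build a BEL document (and its sidecar) from converted statements
#'
#' One evidence block is created per sentence bearing at least one
#' statement; blocks are ordered by (passage order, sentence span) and
#' statements within a block by their canonical serialization, so identical
#' inputs produce byte-identical documents. The sidecar carries, per
#' statement, the entity text locations and alternative namespace
#' candidates that cannot be coded in BEL but matter for curation.
#'
#' @param statements Statement-level tibble from [events_to_statements()];
#'   every row must carry its evidence sentence (an `NA` sentence is an
#'   error).
#' @param annotations Named list applied to every block
#'   (e.g. `list(Species = "10090")` for an ApoE-deficient mouse corpus).
#' @param name,description,version Document header fields.
#' @param namespaces Named character vector of namespace URLs; defaults to
#'   `"-"` for every namespace observed in the statements.
#' @return A list with elements `document` (a [bel_document()]) and
#'   `sidecar` (a list of per-statement records, aligned 1:1 with the
#'   document's statements in order).
#' @export
build_document <- function(statements, annotations = list(),
                           name = "belminer extraction", description = "",
                           version = "1.0", namespaces = NULL) {
  if (nrow(statements) == 0L) {
    doc <- bel_document(name = name, description = description,
                        version = version)
    return(list(document = doc, sidecar = list()))
  }
  if (any(is.na(statements$sentence))) {
    abort("statement without an evidence sentence",
          class = "bel_conversion_error")
  }
  used_ns <- unique(unlist(lapply(statements$statement,
                                  statement_namespaces)))
  if (is.null(namespaces)) {
    namespaces <- stats::setNames(rep("-", length(used_ns)), used_ns)
  }
  bad_keys <- setdiff(names(annotations), standard_annotation_keys)
  # deterministic ordering: passage order, sentence span, serialization
  statements$serialized <- vapply(statements$statement,
                                  serialize_statement, character(1L))
  ord <- order(match(statements$pmid, unique(statements$pmid)),
               statements$start, statements$serialized)
  statements <- statements[ord, , drop = FALSE]
  keys <- paste(statements$pmid, statements$start, statements$end)
  blocks <- list()
  sidecar <- list()
  stmt_index <- 0L
  for (k in unique(keys)) {
    grp <- statements[keys == k, , drop = FALSE]
    ev <- bel_evidence(grp$sentence[1L], pmid = grp$pmid[1L],
                       section = grp$section[1L],
                       span = c(grp$start[1L], grp$end[1L]))
    blocks[[length(blocks) + 1L]] <- bel_block(
      ev, annotations = annotations, statements = grp$statement)
    for (j in seq_len(nrow(grp))) {
      stmt_index <- stmt_index + 1L
      men <- grp$mentions[[j]]
      sidecar[[stmt_index]] <- list(
        statement_index = stmt_index,
        statement = grp$serialized[j],
        evidence_span = c(grp$start[1L], grp$end[1L]),
        mentions = mention_sidecar(men))
    }
  }
  ann_defs <- character()
  if (length(bad_keys)) {
    ann_defs <- stats::setNames(rep(".*", length(bad_keys)), bad_keys)
  }
  doc <- bel_document(name = name, description = description,
                      version = version, namespaces = namespaces,
                      annotations = ann_defs, blocks = blocks)
  list(document = doc, sidecar = sidecar)
}

mention_sidecar <- function(men) {
  if (is.null(men) || nrow(men) == 0L) return(list())
  out <- list()
  if (!is.na(men$cause_id[1L])) {
    out[[length(out) + 1L]] <- list(
      role = "cause", span = c(men$cause_start[1L], men$cause_end[1L]),
      text = men$cause_text[1L],
      namespace = men$cause_namespace[1L], id = men$cause_id[1L],
      alternatives = list())
  }
  out[[length(out) + 1L]] <- list(
    role = "theme", span = c(men$theme_start[1L], men$theme_end[1L]),
    text = men$theme_text[1L],
    namespace = men$theme_namespace[1L], id = men$theme_id[1L],
    alternatives = list())
  out
}

#' Write / read the JSON sidecar
#'
#' @param sidecar Sidecar list from [build_document()].
#' @param path File path.
#' @return `read_sidecar()` returns the sidecar list.
#' @export
write_sidecar <- function(sidecar, path) {
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# ---------------------------------------------------------------------------
# Curation edits

#' Construct a curation edit
#'
#' @param kind One of `"accept"`, `"reject"`, `"modify_statement"`,
#'   `"assemble_fragments"`, `"set_annotation"`.
#' @param targets Statement indices (1-based, document order); for
#'   `assemble_fragments` exactly two (one subject--relation and one
#'   relation--object fragment); for `set_annotation` the statements whose
#'   blocks receive the annotation.
#' @param payload For `modify_statement` the replacement statement text; for
#'   `set_annotation` a list `list(key =, value =)`.
#' @return An object of class `curation_edit`.
#' @export
curation_edit <- function(kind = c("accept", "reject", "modify_statement",
                                   "assemble_fragments", "set_annotation"),
                          targets, payload = NULL) {
  kind <- match.arg(kind)
  if (kind == "assemble_fragments" && length(targets) != 2L) {
    abort("assemble_fragments targets exactly two fragments")
  }
  structure(list(kind = kind, targets = as.integer(targets),
                 payload = payload), class = "curation_edit")
}

#' Apply curation edits to a BEL document
#'
#' The input document is never mutated: edits produce a modified copy, as
#' the curation interface preserves the original and works on a copy. Every
#' surviving statement is re-validated; an edit that would introduce an
#' invalid statement is refused with the validator's violation list.
#' Rejected statements are removed (their block disappears when empty);
#' assembling a subject--relation fragment with a relation--object fragment
#' whose relations agree yields one complete statement in the first
#' fragment's block.
#'
#' @param doc A [bel_document()].
#' @param edits A list of [curation_edit()] objects (a single edit is
#'   accepted too).
#' @return The edited [bel_document()]; guaranteed to pass
#'   [validate_document()].
#' @export
apply_edits <- function(doc, edits) {
  stopifnot(inherits(doc, "bel_document"))
  if (inherits(edits, "curation_edit")) edits <- list(edits)
  out <- doc  # R copy semantics: `doc` itself is untouched
  for (e in edits) {
    out <- apply_one_edit(out, e)
  }
  v <- validate_document(out)
  if (nrow(v)) {
    abort(paste0("edited document does not validate: ", v$message[1L]),
          class = "bel_validation_error", violations = v)
  }
  out
}

locate_statement <- function(doc, index) {
  flat <- document_statements(doc)
  if (index < 1L || index > length(flat)) {
    abort(sprintf("statement index %d out of range (document has %d)",
                  index, length(flat)), class = "bel_edit_error")
  }
  flat[[index]]
}

set_statement_at <- function(doc, index, value) {
  # value NULL removes the statement; empty blocks are dropped
  idx <- 0L
  for (b in seq_along(doc$blocks)) {
    for (k in seq_along(doc$blocks[[b]]$statements)) {
      idx <- idx + 1L
      if (idx == index) {
        if (is.null(value)) {
          doc$blocks[[b]]$statements[[k]] <- NULL
        } else {
          doc$blocks[[b]]$statements[[k]] <- value
        }
        doc$blocks <- keep(doc$blocks, function(x) length(x$statements) > 0L)
        return(doc)
      }
    }
  }
  abort("statement index out of range", class = "bel_edit_error")
}

apply_one_edit <- function(doc, e) {
  stopifnot(inherits(e, "curation_edit"))
  if (e$kind == "accept") {
    locate_statement(doc, e$targets[1L])  # index check only
    return(doc)
  }
  if (e$kind == "reject") {
    for (t in sort(e$targets, decreasing = TRUE)) {
      locate_statement(doc, t)
      doc <- set_statement_at(doc, t, NULL)
    }
    return(doc)
  }
  if (e$kind == "modify_statement") {
    locate_statement(doc, e$targets[1L])
    s <- tryCatch(parse_statement(e$payload), error = function(err) {
      abort(paste0("modify_statement refused, replacement does not parse: ",
                   conditionMessage(err)), class = "bel_edit_error")
    })
    v <- validate_statement(s, doc)
    if (nrow(v)) {
      abort(paste0("modify_statement refused: ", v$message[1L]),
            class = "bel_edit_error", violations = v)
    }
    return(set_statement_at(doc, e$targets[1L], s))
  }
  if (e$kind == "assemble_fragments") {
    a <- locate_statement(doc, e$targets[1L])
    b <- locate_statement(doc, e$targets[2L])
    frags <- c(a$statement$fragment_kind, b$statement$fragment_kind)
    if (sort(frags)[1L] != "relation_object" ||
        sort(frags)[2L] != "subject_relation") {
      abort(paste0("assemble_fragments needs one subject_relation and one ",
                   "relation_object fragment"), class = "bel_edit_error")
    }
    sr <- if (frags[1L] == "subject_relation") a else b
    ro <- if (frags[1L] == "subject_relation") b else a
    if (sr$statement$relation != ro$statement$relation) {
      abort("assemble_fragments refused: fragment relations disagree",
            class = "bel_edit_error")
    }
    s <- bel_statement(sr$statement$subject, sr$statement$relation,
                       ro$statement$object)
    v <- validate_statement(s, doc)
    if (nrow(v)) {
      abort(paste0("assemble_fragments refused: ", v$message[1L]),
            class = "bel_edit_error", violations = v)
    }
    first <- min(e$targets)
    second <- max(e$targets)
    doc <- set_statement_at(doc, second, NULL)
    doc <- set_statement_at(doc, first, s)
    return(doc)
  }
  # set_annotation
  key <- e$payload$key
  if (!key %in% names(doc$annotations)) {
    abort(sprintf("set_annotation refused: key '%s' is not defined", key),
          class = "bel_edit_error")
  }
  for (t in e$targets) {
    loc <- locate_statement(doc, t)
    doc$blocks[[loc$block]]$annotations[[key]] <- e$payload$value
  }
  doc
}

#' Read a curation-edit script (JSON lines)
#'
#' Each line is one JSON object with fields `kind`, `targets` and optional
#' `payload`.
#'
#' @param path File path.
#' @return A list of [curation_edit()] objects.
#' @export
read_edit_script <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(str_trim(lines))]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    curation_edit(x$kind, unlist(x$targets), x$payload)
  })
}
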