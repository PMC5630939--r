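# Text preparation, dictionary NER and trigger-pattern event extraction.
# The NER and event extractors are rule-based stand-ins with the same output
# contracts as heavy-weight taggers (dictionary longest-match recognition;
# positive/negative regulation events with cause/theme arguments), so the
# downstream BEL converter is fully testable; an adapter producing the same
# mention/event tables can replace them.

#' Clean raw article text for machine parsing
#'
#' Rejoins words hyphenated across line breaks, converts in-paragraph
#' newlines to spaces, strips control characters, normalizes smart quotes,
#' dashes and common ligatures to ASCII, and collapses runs of whitespace.
#' Idempotent: cleaning a clean string is the identity.
#'
#' @param raw A character vector of raw text.
#' @return The cleaned character vector.
#' @export
#' @examples
#' clean_text("athero-\nsclerosis")
clean_text <- function(raw) {
  x <- raw
  # ligatures frequently produced by PDF-to-text conversion
  x <- str_replace_all(x, c("ﬀ" = "ff", "ﬁ" = "fi",
                            "ﬂ" = "fl", "ﬃ" = "ffi",
                            "ﬄ" = "ffl"))
  x <- normalize_quotes(x)
  # de-hyphenation at line breaks: "athero-\nsclerosis" -> "atherosclerosis"
  x <- gsub("([A-Za-z])-[ \t]*\r?\n[ \t]*([a-z])", "\\1\\2", x)
  x <- gsub("\r?\n", " ", x)
  x <- gsub("[\x01-\x08\x0b\x0c\x0e-\x1f\x7f]", "", x, useBytes = FALSE)
  x <- gsub("[ \t]+", " ", x)
  str_trim(x)
}

.retained_sections <- c("abstract", "methods", "results")

#' Build a passage table
#'
#' @param pmid,section,text Vectors of equal length (section one of abstract,
#'   methods, results, introduction, discussion, conclusion, other).
#' @param clean Clean the text with [clean_text()] (default `TRUE`).
#' @return A tibble with columns `pmid`, `section`, `text` and a `sentences`
#'   list-column (filled by [segment_sentences()], `NULL` until then).
#' @export
passage_table <- function(pmid, section, text, clean = TRUE) {
  section <- tolower(section)
  known <- c(.retained_sections, "introduction", "discussion", "conclusion",
             "other")
  bad <- setdiff(unique(section), known)
  if (length(bad)) abort(paste0("unknown section label: ",
                                paste(bad, collapse = ", ")))
  tibble(pmid = as.character(pmid), section = section,
         text = if (clean) clean_text(text) else text,
         sentences = vector("list", length(text)))
}

#' Keep only the sections used for causal-knowledge extraction
#'
#' Introduction, discussion and conclusion sections are dropped: they mostly
#' contain non-causal evidence, repetition of results and hypotheses.
#' Abstract, methods and results passages are retained in their input order.
#'
#' @param passages A passage tibble from [passage_table()].
#' @return The filtered tibble. A warning names any article for which no
#'   passage was retained.
#' @export
select_sections <- function(passages) {
  keep <- passages$section %in% .retained_sections
  dropped_all <- setdiff(unique(passages$pmid), unique(passages$pmid[keep]))
  if (length(dropped_all)) {
    warn(paste0("no retained passages for article(s): ",
                paste(dropped_all, collapse = ", ")))
  }
  passages[keep, , drop = FALSE]
}

.abbreviations <- c("et al", "e\\.g", "i\\.e", "cf", "vs", "ca", "approx",
                    "Fig", "Figs", "Tab", "Ref", "No", "Dr", "St", "resp")

#' Segment passage text into sentences
#'
#' Splits on sentence-final punctuation followed by whitespace and an
#' upper-case letter, digit or opening parenthesis, protecting common
#' abbreviations ("et al.", "Fig.", "e.g.") and decimal numbers. Sentence
#' spans are 0-based half-open character offsets into the cleaned text.
#'
#' @param passages A passage tibble from [passage_table()].
#' @return The same tibble with the `sentences` list-column filled: each
#'   element a tibble with columns `sentence_id`, `start`, `end`, `text`.
#' @export
segment_sentences <- function(passages) {
  passages$sentences <- lapply(passages$text, split_sentences)
  passages
}

split_sentences <- function(text) {
  if (!nzchar(text)) {
    return(tibble(sentence_id = integer(), start = integer(),
                  end = integer(), text = character()))
  }
  # candidate boundaries: [.!?] + space + sentence-initial character
  m <- gregexpr("[.!?]+(?=[ ][A-Z0-9(])", text, perl = TRUE)[[1L]]
  cuts <- integer()
  if (m[1L] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      before <- substr(text, max(1L, e - 12L), e - 1L)
      # protect "et al.", "Fig. 3", initials etc.
      pat <- paste0("\\b(", paste(.abbreviations, collapse = "|"),
                    ")$|\\b[A-Z]$")
      if (grepl(pat, before)) next
      cuts <- c(cuts, e)
    }
  }
  starts <- c(1L, cuts + 2L)
  ends <- c(cuts, nchar(text))
  out <- list()
  sid <- 0L
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    chunk <- substr(text, s, e)
    lead <- nchar(chunk) - nchar(sub("^\\s+", "", chunk))
    trail <- nchar(chunk) - nchar(sub("\\s+$", "", chunk))
    s <- s + lead; e <- e - trail
    if (e < s) next
    sid <- sid + 1L
    out[[sid]] <- tibble(sentence_id = sid, start = s - 1L, end = e,
                         text = substr(text, s, e))
  }
  if (!length(out)) {
    return(tibble(sentence_id = integer(), start = integer(),
                  end = integer(), text = character()))
  }
  bind_rows(out)
}

# ---------------------------------------------------------------------------
# Dictionaries

.default_bel_class <- c(
  HGNC = "gene_protein", MGI = "gene_protein", CHEBI = "chemical",
  SCHEM = "chemical", CHEMBL = "chemical", GOBP = "process", GO = "process",
  MESHD = "process", SCOMP = "complex", SFAM = "family"
)

#' Load an entity dictionary from TSV
#'
#' Expected columns: `id`, `preferred_name`, `synonyms` (pipe-separated,
#' may be empty), `namespace`. A synonym mapping to two identifiers within
#' one dictionary is a collision and is rejected at load time.
#'
#' @param path TSV file path.
#' @param namespace Override the namespace keyword (default: from the file).
#' @param bel_class Entity class for terms from this dictionary; default is
#'   derived from the namespace (HGNC/MGI gene_protein, CHEBI/SCHEM/CHEMBL
#'   chemical, GOBP/GO/MESHD process, SCOMP complex, SFAM family).
#' @param case_policy `"case-insensitive-long-words"` (default: tokens of
#'   more than 4 characters match case-insensitively, short tokens such as
#'   gene symbols match exactly) or `"exact"`.
#' @return An object of class `bel_dictionary`.
#' @export
read_dictionary <- function(path, namespace = NULL, bel_class = NULL,
                            case_policy = c("case-insensitive-long-words",
                                            "exact")) {
  case_policy <- match.arg(case_policy)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  need <- c("id", "preferred_name", "synonyms", "namespace")
  if (!all(need %in% names(raw))) {
    abort(paste0("dictionary TSV must have columns: ",
                 paste(need, collapse = ", ")))
  }
  ns <- toupper(namespace %||% raw$namespace[1L])
  entries <- lapply(seq_len(nrow(raw)), function(i) {
    syn <- strsplit(raw$synonyms[i], "|", fixed = TRUE)[[1L]]
    syn <- syn[nzchar(syn)]
    tibble(id = raw$id[i], synonym = unique(c(raw$preferred_name[i], syn)))
  })
  entries <- bind_rows(entries)
  bel_dictionary(ns, entries, bel_class = bel_class,
                 case_policy = case_policy)
}

#' Construct a dictionary from an id/synonym table
#'
#' @param namespace Namespace keyword.
#' @param entries Tibble with columns `id`, `synonym` (the preferred name
#'   must be included among the synonyms of its id).
#' @inheritParams read_dictionary
#' @return An object of class `bel_dictionary`.
#' @export
bel_dictionary <- function(namespace, entries,
                           bel_class = NULL,
                           case_policy = c("case-insensitive-long-words",
                                           "exact")) {
  case_policy <- match.arg(case_policy)
  namespace <- toupper(namespace)
  stopifnot(all(c("id", "synonym") %in% names(entries)))
  entries <- distinct(as_tibble(entries[, c("id", "synonym")]))
  if (any(!nzchar(entries$synonym))) abort("empty synonym in dictionary")
  key <- synonym_key(entries$synonym, case_policy)
  dup <- unique(key[duplicated(key)])
  coll <- entries[key %in% dup, , drop = FALSE]
  coll_ids <- tapply(coll$id, synonym_key(coll$synonym, case_policy),
                     function(x) length(unique(x)))
  if (any(coll_ids > 1L)) {
    bad <- names(coll_ids)[coll_ids > 1L]
    abort(paste0("dictionary collision: synonym(s) mapping to multiple ids: ",
                 paste(bad, collapse = ", ")),
          class = "bel_dictionary_error")
  }
  entries <- entries[!duplicated(key), , drop = FALSE]
  structure(
    list(namespace = namespace, entries = entries,
         bel_class = bel_class %||% unname(.default_bel_class[namespace]) %||%
           "gene_protein",
         case_policy = case_policy),
    class = "bel_dictionary"
  )
}

#' @export
print.bel_dictionary <- function(x, ...) {
  cat("<bel_dictionary> ", x$namespace, " (", x$bel_class, "): ",
      length(unique(x$entries$id)), " ids, ", nrow(x$entries),
      " synonyms\n", sep = "")
  invisible(x)
}

synonym_key <- function(syn, case_policy) {
  if (case_policy == "exact") return(syn)
  ifelse(nchar(syn) <= 4L, syn, tolower(syn))
}

#' Bundled excerpt dictionaries
#'
#' Small hand-assembled excerpts of HGNC gene symbols, GO biological-process
#' terms and ChEBI-style chemical names shipped with the package for the
#' fixtures generator, examples and tests. They are excerpts, not full
#' vocabularies.
#'
#' @param namespaces Which of `"HGNC"`, `"GOBP"`, `"CHEBI"` to load.
#' @return A named list of `bel_dictionary` objects in priority order.
#' @export
bundled_dictionaries <- function(namespaces = c("HGNC", "GOBP", "CHEBI")) {
  files <- c(HGNC = "hgnc_excerpt.tsv", GOBP = "gobp_excerpt.tsv",
             CHEBI = "chebi_excerpt.tsv")
  out <- lapply(namespaces, function(ns) {
    path <- system.file("extdata", files[[ns]], package = "belminer",
                        mustWork = TRUE)
    read_dictionary(path)
  })
  stats::setNames(out, namespaces)
}

# ---------------------------------------------------------------------------
# NER

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

dictionary_pattern <- function(dict) {
  syn <- dict$entries$synonym
  syn <- syn[order(-nchar(syn), syn)]  # longest alternative wins at a position
  alts <- vapply(seq_along(syn), function(i) {
    pat <- escape_regex(syn[i])
    if (dict$case_policy == "case-insensitive-long-words" &&
        nchar(syn[i]) > 4L) {
      pat <- paste0("(?i:", pat, ")")
    }
    pat
  }, character(1L))
  paste0("(?<![A-Za-z0-9_])(?:", paste(alts, collapse = "|"),
         ")(?![A-Za-z0-9_])")
}

dictionary_lookup <- function(dict, matched) {
  key <- synonym_key(dict$entries$synonym, dict$case_policy)
  mkey <- synonym_key(matched, dict$case_policy)
  dict$entries$id[match(mkey, key)]
}

empty_mentions <- function() {
  tibble(start = integer(), end = integer(), matched_text = character(),
         namespace = character(), id = character(), bel_class = character())
}

#' Dictionary-based named-entity recognition
#'
#' Token-boundary-anchored longest match against one or more dictionaries.
#' Overlapping candidates are resolved by longer span first, then by the
#' order of `dictionaries` (priority). Each mention is normalized to the
#' preferred identifier of the matching dictionary entry. Deterministic:
#' identical sentence and dictionaries give identical mentions.
#'
#' @param sentence A single sentence string.
#' @param dictionaries A list of `bel_dictionary` objects in priority order.
#' @return A tibble of mentions: `start`, `end` (0-based half-open offsets
#'   into the sentence), `matched_text`, `namespace`, `id`, `bel_class`.
#' @export
#' @examples
#' dicts <- bundled_dictionaries()
#' ner("CYP4A11 transfection significantly increased microvessel density",
#'     dicts)
ner <- function(sentence, dictionaries) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  if (inherits(dictionaries, "bel_dictionary")) {
    dictionaries <- list(dictionaries)
  }
  cand <- list()
  for (pri in seq_along(dictionaries)) {
    dict <- dictionaries[[pri]]
    pat <- dictionary_pattern(dict)
    m <- gregexpr(pat, sentence, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    matched <- substring(sentence, starts, starts + lens - 1L)
    cand[[length(cand) + 1L]] <- tibble(
      start = starts - 1L, end = starts + lens - 1L,
      matched_text = matched, namespace = dict$namespace,
      id = dictionary_lookup(dict, matched), bel_class = dict$bel_class,
      priority = pri, len = lens
    )
  }
  if (!length(cand)) return(empty_mentions())
  cand <- bind_rows(cand)
  cand <- cand[order(-cand$len, cand$priority, cand$start), , drop = FALSE]
  taken <- logical(nchar(sentence))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):cand$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$priority <- NULL
  out$len <- NULL
  out
}

# ---------------------------------------------------------------------------
# Events

#' Default regulation trigger lexicon
#'
#' Verbs signalling positive or negative regulation; matching covers simple
#' inflections (increase/increases/increased/increasing).
#'
#' @return A tibble with columns `word` and `type`
#'   (`Positive_regulation` / `Negative_regulation`).
#' @export
default_trigger_lexicon <- function() {
  tibble(
    word = c("increase", "induce", "promote", "upregulate", "enhance",
             "decrease", "inhibit", "reduce", "suppress", "downregulate"),
    type = rep(c("Positive_regulation", "Negative_regulation"), each = 5L)
  )
}

trigger_pattern <- function(word) {
  stem <- sub("e$", "", word)
  paste0("(?<![A-Za-z])(?i:", escape_regex(stem), "(?:e|es|ed|ing|s)?)",
         "(?![A-Za-z])")
}

empty_events <- function() {
  tibble(type = character(), trigger = character(),
         trigger_start = integer(), trigger_end = integer(),
         cause_namespace = character(), cause_id = character(),
         cause_class = character(), cause_start = integer(),
         cause_end = integer(), cause_text = character(),
         theme_namespace = character(), theme_id = character(),
         theme_class = character(), theme_start = integer(),
         theme_end = integer(), theme_text = character())
}

#' Trigger-pattern regulation-event extraction
#'
#' For each regulation trigger found in the sentence, the theme is the
#' nearest mention starting after the trigger and the cause the nearest
#' mention ending before it; events never cross a sentence boundary (the
#' unit of processing is one sentence). Triggers without a theme yield no
#' event. Negated triggers ("did not increase") yield no event by default;
#' with `negation = "causesNoChange"` they are emitted with type
#' `No_regulation` for downstream mapping to the causesNoChange relation.
#'
#' @param sentence A single sentence string.
#' @param mentions Mention tibble from [ner()] for the same sentence.
#' @param triggers Trigger lexicon tibble (`word`, `type`); defaults to
#'   [default_trigger_lexicon()].
#' @param negation `"drop"` (default) or `"causesNoChange"`.
#' @return A tibble of events, one row per (trigger, cause, theme); cause
#'   columns are `NA` when no cause precedes the trigger (the event converts
#'   to a relation--object fragment downstream).
#' @export
extract_events <- function(sentence, mentions,
                           triggers = default_trigger_lexicon(),
                           negation = c("drop", "causesNoChange")) {
  negation <- match.arg(negation)
  if (is.null(mentions) || nrow(mentions) == 0L) return(empty_events())
  hits <- list()
  for (i in seq_len(nrow(triggers))) {
    m <- gregexpr(trigger_pattern(triggers$word[i]), sentence,
                  perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    hits[[length(hits) + 1L]] <- tibble(
      type = triggers$type[i],
      trigger = substring(sentence, starts, starts + lens - 1L),
      trigger_start = starts - 1L, trigger_end = starts + lens - 1L)
  }
  if (!length(hits)) return(empty_events())
  hits <- bind_rows(hits)
  hits <- hits[order(hits$trigger_start), , drop = FALSE]

  out <- list()
  for (i in seq_len(nrow(hits))) {
    ts <- hits$trigger_start[i]; te <- hits$trigger_end[i]
    before <- substr(sentence, max(1L, ts - 25L), ts)
    negated <- grepl("\\b(not|no|neither|never)\\s+(\\w+\\s+){0,2}$", before,
                     perl = TRUE)
    if (negated && negation == "drop") next
    themes <- mentions[mentions$start >= te, , drop = FALSE]
    if (!nrow(themes)) next
    theme <- themes[which.min(themes$start), , drop = FALSE]
    causes <- mentions[mentions$end <= ts, , drop = FALSE]
    cause <- if (nrow(causes)) causes[which.max(causes$end), , drop = FALSE]
    out[[length(out) + 1L]] <- tibble(
      type = if (negated) "No_regulation" else hits$type[i],
      trigger = hits$trigger[i], trigger_start = ts, trigger_end = te,
      cause_namespace = if (is.null(cause)) NA_character_ else cause$namespace,
      cause_id = if (is.null(cause)) NA_character_ else cause$id,
      cause_class = if (is.null(cause)) NA_character_ else cause$bel_class,
      cause_start = if (is.null(cause)) NA_integer_ else cause$start,
      cause_end = if (is.null(cause)) NA_integer_ else cause$end,
      cause_text = if (is.null(cause)) NA_character_ else cause$matched_text,
      theme_namespace = theme$namespace, theme_id = theme$id,
      theme_class = theme$bel_class, theme_start = theme$start,
      theme_end = theme$end, theme_text = theme$matched_text)
  }
  if (!length(out)) return(empty_events())
  bind_rows(out)
}

# ---------------------------------------------------------------------------
# Recall evaluation

#' Evaluate NER recall against a gold standard
#'
#' A found mention matches a gold mention when sentence, span, namespace and
#' identifier all agree. Recall per namespace is
#' `|gold matched| / |gold|`; precision is reported alongside.
#'
#' @param found,gold Mention tibbles carrying at least `sentence_key`
#'   (any sentence identifier shared between the two tables), `start`,
#'   `end`, `namespace`, `id`.
#' @param namespaces Namespaces to evaluate (default: all in `gold`); an
#'   empty gold standard for a requested namespace is an error.
#' @return A tibble with one row per namespace plus an `overall` row:
#'   `namespace`, `n_gold`, `n_found`, `n_matched`, `recall_pct`,
#'   `precision_pct`.
#' @export
evaluate_recall <- function(found, gold, namespaces = NULL) {
  need <- c("sentence_key", "start", "end", "namespace", "id")
  if (!all(need %in% names(gold)) || !all(need %in% names(found))) {
    abort(paste0("found and gold need columns: ",
                 paste(need, collapse = ", ")))
  }
  namespaces <- namespaces %||% unique(gold$namespace)
  missing <- setdiff(namespaces, unique(gold$namespace))
  if (length(missing) || nrow(gold) == 0L) {
    abort(paste0("gold standard is empty for namespace(s): ",
                 paste(if (nrow(gold) == 0L) namespaces else missing,
                       collapse = ", ")))
  }
  gold <- distinct(gold[gold$namespace %in% namespaces, need])
  found <- distinct(found[found$namespace %in% namespaces, need])
  matched <- semi_join(gold, found, by = need)
  per_ns <- function(tbl, ns) sum(tbl$namespace == ns)
  rows <- lapply(namespaces, function(ns) {
    ng <- per_ns(gold, ns); nf <- per_ns(found, ns); nm <- per_ns(matched, ns)
    tibble(namespace = ns, n_gold = ng, n_found = nf, n_matched = nm,
           recall_pct = 100 * nm / ng,
           precision_pct = if (nf > 0L) 100 * nm / nf else NA_real_)
  })
  overall <- tibble(
    namespace = "overall", n_gold = nrow(gold), n_found = nrow(found),
    n_matched = nrow(matched),
    recall_pct = 100 * nrow(matched) / nrow(gold),
    precision_pct = if (nrow(found) > 0L)
      100 * nrow(matched) / nrow(found) else NA_real_)
  bind_rows(c(rows, list(overall)))
}
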