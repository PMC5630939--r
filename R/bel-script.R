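# BEL Script reader/writer: line-oriented SET/DEFINE dialect.
#   SET DOCUMENT Name = "..." | DEFINE NAMESPACE KW AS URL "..."
#   DEFINE ANNOTATION Key AS PATTERN "..." | SET Evidence = "..."
#   SET PMID/Section/Span = "..." | SET <AnnotationKey> = "..." | UNSET ALL
# Statement lines are anything else. Evidence starts a new block.

bs_quote <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

bs_unquote <- function(x) {
  m <- regmatches(x, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*$', x))[[1L]]
  if (length(m) < 2L) return(NULL)
  y <- m[2L]
  y <- gsub("\\\\\"", "\"", y)
  gsub("\\\\\\\\", "\\\\", y)
}

#' Write a BEL document in BEL Script format
#'
#' @param doc A validated [bel_document()].
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The BEL Script text, invisibly when written to a file.
#' @export
write_bel_script <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "bel_document"))
  v <- validate_document(doc)
  if (nrow(v)) {
    abort(paste0("document does not validate; first violation: ",
                 v$message[1L]), class = "bel_validation_error")
  }
  out <- c(
    paste0("SET DOCUMENT Name = ", bs_quote(doc$header$name)),
    paste0("SET DOCUMENT Description = ", bs_quote(doc$header$description)),
    paste0("SET DOCUMENT Version = ", bs_quote(doc$header$version)),
    ""
  )
  for (ns in names(doc$namespaces)) {
    out <- c(out, paste0("DEFINE NAMESPACE ", ns, " AS URL ",
                         bs_quote(doc$namespaces[[ns]])))
  }
  extra_ann <- doc$annotations[setdiff(names(doc$annotations),
                                       standard_annotation_keys)]
  for (k in names(extra_ann)) {
    out <- c(out, paste0("DEFINE ANNOTATION ", k, " AS PATTERN ",
                         bs_quote(extra_ann[[k]])))
  }
  out <- c(out, "")
  for (blk in doc$blocks) {
    ev <- blk$evidence
    out <- c(out, paste0("SET Evidence = ", bs_quote(ev$text)))
    if (!is.na(ev$pmid)) out <- c(out, paste0("SET PMID = ", bs_quote(ev$pmid)))
    if (!is.na(ev$section)) {
      out <- c(out, paste0("SET Section = ", bs_quote(ev$section)))
    }
    if (!is.null(ev$span)) {
      out <- c(out, paste0("SET Span = ",
                           bs_quote(paste(ev$span, collapse = ":"))))
    }
    for (k in names(blk$annotations)) {
      out <- c(out, paste0("SET ", k, " = ", bs_quote(blk$annotations[[k]])))
    }
    for (s in blk$statements) out <- c(out, serialize_statement(s))
    out <- c(out, "UNSET ALL", "")
  }
  text <- paste(out, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, useBytes = TRUE)
  invisible(text)
}

script_error <- function(msg, line) {
  abort(sprintf("BEL Script error at line %d: %s", line, msg),
        class = "bel_script_error", line = line)
}

#' Read a BEL document from BEL Script text
#'
#' @param text BEL Script content as a single string, a character vector of
#'   lines, or a path to a `.bel` file.
#' @return A [bel_document()]. Undefined annotation keys and undeclared
#'   namespaces are errors (with the offending line number).
#' @export
read_bel_script <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE, encoding = "UTF-8")
  } else if (length(text) == 1L) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  header <- list(name = "untitled", description = "", version = "1.0")
  namespaces <- character()
  ann_defs <- character()
  blocks <- list()
  cur <- NULL  # current block under construction
  cur_ann <- list()

  flush_block <- function() {
    if (!is.null(cur)) {
      blocks[[length(blocks) + 1L]] <<- cur
      cur <<- NULL
    }
  }

  reserved <- c("Evidence", "PMID", "Section", "Span")
  for (ln in seq_along(text)) {
    line <- str_trim(text[ln])
    if (!nzchar(line) || startsWith(line, "#")) next

    if (grepl("^SET DOCUMENT ", line)) {
      m <- regmatches(line, regexec("^SET DOCUMENT (\\w+) = (.*)$", line))[[1L]]
      if (length(m) < 3L) script_error("malformed SET DOCUMENT", ln)
      val <- bs_unquote(m[3L])
      if (is.null(val)) script_error("malformed quoted value", ln)
      header[[tolower(m[2L])]] <- val
    } else if (grepl("^DEFINE NAMESPACE ", line)) {
      m <- regmatches(line, regexec(
        "^DEFINE NAMESPACE (\\w+) AS URL (.*)$", line))[[1L]]
      if (length(m) < 3L) script_error("malformed DEFINE NAMESPACE", ln)
      val <- bs_unquote(m[3L])
      if (is.null(val)) script_error("malformed quoted value", ln)
      namespaces[[toupper(m[2L])]] <- val
    } else if (grepl("^DEFINE ANNOTATION ", line)) {
      m <- regmatches(line, regexec(
        "^DEFINE ANNOTATION (\\w+) AS PATTERN (.*)$", line))[[1L]]
      if (length(m) < 3L) script_error("malformed DEFINE ANNOTATION", ln)
      val <- bs_unquote(m[3L])
      if (is.null(val)) script_error("malformed quoted value", ln)
      ann_defs[[m[2L]]] <- val
    } else if (grepl("^UNSET\\b", line)) {
      flush_block()
      cur_ann <- list()
    } else if (grepl("^SET ", line)) {
      m <- regmatches(line, regexec("^SET (\\w+) = (.*)$", line))[[1L]]
      if (length(m) < 3L) script_error("malformed SET", ln)
      key <- m[2L]
      val <- bs_unquote(m[3L])
      if (is.null(val)) script_error("malformed quoted value", ln)
      if (key == "Evidence") {
        flush_block()
        cur <- bel_block(bel_evidence(val), annotations = cur_ann)
      } else if (key %in% reserved) {
        if (is.null(cur)) script_error(paste0("SET ", key,
                                              " before SET Evidence"), ln)
        if (key == "PMID") cur$evidence$pmid <- val
        if (key == "Section") cur$evidence$section <- val
        if (key == "Span") {
          cur$evidence$span <- as.integer(strsplit(val, ":", fixed = TRUE)[[1L]])
        }
      } else {
        if (!key %in% c(standard_annotation_keys, names(ann_defs))) {
          script_error(sprintf("annotation key '%s' is not defined", key), ln)
        }
        cur_ann[[key]] <- val
        if (!is.null(cur)) cur$annotations[[key]] <- val
      }
    } else {
      s <- tryCatch(parse_statement(line), error = function(e) {
        script_error(paste0("statement does not parse: ",
                            conditionMessage(e)), ln)
      })
      used <- statement_namespaces(s)
      und <- setdiff(used, names(namespaces))
      if (length(und)) {
        script_error(sprintf("undeclared namespace %s",
                             paste(und, collapse = ", ")), ln)
      }
      if (is.null(cur)) script_error("statement before SET Evidence", ln)
      cur$statements[[length(cur$statements) + 1L]] <- s
    }
  }
  flush_block()
  bel_document(name = header$name, description = header$description,
               version = header$version, namespaces = namespaces,
               annotations = ann_defs, blocks = blocks)
}
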