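# End-to-end workflow runner: clean -> section filter -> sentence
# segmentation -> NER + events -> BEL conversion -> document/sidecar ->
# KAM compile -> XGMML export -> topology reports, with a manifest of
# artifact content hashes for reproducible runs.

#' Pipeline run configuration
#'
#' @param passages A passage tibble ([passage_table()]); alternatively
#'   `input` may point to files.
#' @param input Optional character vector of plain-text passage files; each
#'   file needs a JSON sidecar `<file>.json` with fields `pmid` and
#'   `section`.
#' @param dictionaries Dictionaries in priority order.
#' @param triggers Trigger lexicon (see [extract_events()]).
#' @param annotations Document-wide annotation list
#'   (e.g. `list(Species = "10090")`).
#' @param edits Optional list of [curation_edit()] objects (or path to a
#'   JSON-lines edit script) applied before compilation.
#' @param infer Structural-edge inference toggles (see [compile_kam()]).
#' @param out_dir Output directory for artifacts.
#' @param name Run/document name.
#' @return A list of class `run_config`.
#' @export
run_config <- function(passages = NULL, input = NULL,
                       dictionaries = bundled_dictionaries(),
                       triggers = default_trigger_lexicon(),
                       annotations = list(), edits = NULL,
                       infer = list(), out_dir = tempfile("belminer-run-"),
                       name = "belminer run") {
  structure(list(passages = passages, input = input,
                 dictionaries = dictionaries, triggers = triggers,
                 annotations = annotations, edits = edits, infer = infer,
                 out_dir = out_dir, name = name),
            class = "run_config")
}

read_passage_files <- function(paths) {
  rows <- lapply(paths, function(p) {
    meta_path <- paste0(p, ".json")
    if (!file.exists(meta_path)) {
      abort(paste0("passage file needs a JSON sidecar with pmid/section: ",
                   meta_path), class = "bel_io_error")
    }
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    passage_table(pmid = meta$pmid, section = meta$section,
                  text = paste(readLines(p, warn = FALSE, encoding = "UTF-8"),
                               collapse = "\n"))
  })
  bind_rows(rows)
}

#' Run the knowledge-extraction workflow end to end
#'
#' Stages: text cleaning, section selection, sentence segmentation, NER and
#' event extraction, BEL conversion, document + sidecar emission, optional
#' curation edits, KAM compilation, XGMML export, and topology/census
#' reports. Every artifact is listed in a manifest with its MD5 content
#' hash; identical configurations produce identical manifests.
#'
#' @param cfg A [run_config()].
#' @return A list with the `kam`, the built `document`, `sidecar`,
#'   `reports` and the `manifest` tibble (`artifact`, `path`, `md5`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  passages <- cfg$passages %||% read_passage_files(cfg$input)
  if (is.null(passages) || nrow(passages) == 0L) {
    abort("stage input: no passages to process", class = "bel_io_error")
  }
  passages <- select_sections(passages)
  passages <- segment_sentences(passages)
  utils::write.table(
    passages[, c("pmid", "section", "text")],
    file.path(cfg$out_dir, "passages_clean.tsv"),
    sep = "\t", row.names = FALSE, quote = TRUE)

  extraction <- extract_corpus(passages, cfg$dictionaries, cfg$triggers)
  stmts <- events_to_statements(extraction)
  built <- build_document(stmts, annotations = cfg$annotations,
                          name = cfg$name)
  doc <- built$document
  if (!is.null(cfg$edits)) {
    edits <- if (is.character(cfg$edits)) read_edit_script(cfg$edits)
             else cfg$edits
    doc <- apply_edits(doc, edits)
  }
  xbel_path <- file.path(cfg$out_dir, "statements.xbel")
  write_xbel(doc, xbel_path)
  sidecar_path <- file.path(cfg$out_dir, "statements.sidecar.json")
  write_sidecar(built$sidecar, sidecar_path)

  k <- compile_kam(doc, infer = cfg$infer)
  kam_path <- file.path(cfg$out_dir, "kam.json")
  kam_to_json(k, kam_path)
  xgmml_path <- file.path(cfg$out_dir, "network.xgmml")
  export_xgmml(k, xgmml_path, label = cfg$name)

  dr <- degree_report(k)
  reports <- list(
    node_census = node_census(k),
    edge_census = edge_census(k),
    degree = list(mean_degree = dr$mean_degree,
                  histogram = dr$histogram),
    hubs = find_hubs(dr),
    scale_free = scale_free_check(dr))
  report_path <- file.path(cfg$out_dir, "reports.json")
  jsonlite::write_json(reports, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)

  paths <- c(passages = file.path(cfg$out_dir, "passages_clean.tsv"),
             xbel = xbel_path, sidecar = sidecar_path, kam = kam_path,
             xgmml = xgmml_path, reports = report_path)
  manifest <- tibble(artifact = names(paths), path = unname(paths),
                     md5 = unname(tools::md5sum(unname(paths))))
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(kam = k, document = doc, sidecar = built$sidecar,
       reports = reports, manifest = manifest)
}
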