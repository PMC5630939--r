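event_row <- function(type, cause_ns, cause_id, cause_class,
                      theme_ns, theme_id, theme_class) {
  tibble::tibble(
    type = type, trigger = "x", trigger_start = 0L, trigger_end = 1L,
    cause_namespace = cause_ns, cause_id = cause_id, cause_class = cause_class,
    cause_start = 0L, cause_end = 1L, cause_text = cause_id,
    theme_namespace = theme_ns, theme_id = theme_id,
    theme_class = theme_class, theme_start = 2L, theme_end = 3L,
    theme_text = theme_id)
}

test_that("events map to BEL statements by regulation type and entity class", {
  pos <- event_row("Positive_regulation", "HGNC", "CYP4A11", "gene_protein",
                   "GOBP", "angiogenesis", "process")
  expect_equal(serialize_statement(event_to_statement(pos)), semi_auto_stmt)

  neg <- event_row("Negative_regulation", "HGNC", "CD40LG", "gene_protein",
                   "GOBP", "chemotaxis", "process")
  expect_equal(serialize_statement(event_to_statement(neg)),
               "p(HGNC:CD40LG) -| bp(GOBP:chemotaxis)")

  chem <- event_row("Positive_regulation", "CHEBI", "20-HETE", "chemical",
                    "GOBP", "angiogenesis", "process")
  expect_equal(serialize_statement(event_to_statement(chem)),
               "a(CHEBI:20-HETE) -> bp(GOBP:angiogenesis)")
})

test_that("a cause-less event becomes a relation-object fragment", {
  frag <- event_row("Positive_regulation", NA_character_, NA_character_,
                    NA_character_, "GOBP", "angiogenesis", "process")
  s <- event_to_statement(frag)
  expect_equal(s$fragment_kind, "relation_object")
  expect_equal(serialize_statement(s), "-> bp(GOBP:angiogenesis)")
})

test_that("an unmapped entity class is a conversion error naming the mention", {
  odd <- event_row("Positive_regulation", "HGNC", "A", "gene_protein",
                   "XX", "thing", "weird_class")
  expect_error(event_to_statement(odd), "weird_class",
               class = "bel_conversion_error")
})

test_that("build_document groups statements into one block per sentence", {
  corp <- generate_corpus(generator_config(seed = 14, n_articles = 4))
  ext <- extract_corpus(corp$passages, bundled_dictionaries())
  stmts <- events_to_statements(ext)
  built <- build_document(stmts, annotations = list(Species = "10090"))
  # brute-force: distinct statement-bearing sentences
  n_sent <- nrow(unique(stmts[, c("pmid", "start", "end")]))
  expect_equal(length(built$document$blocks), n_sent)
  expect_equal(length(built$sidecar), nrow(stmts))
  expect_true(all(vapply(built$document$blocks,
                         function(b) identical(b$annotations$Species, "10090"),
                         TRUE)))
  expect_equal(nrow(validate_document(built$document)), 0)
})

test_that("sidecar records align 1:1 with statements and carry spans", {
  corp <- generate_corpus(generator_config(seed = 15, n_articles = 2))
  ext <- extract_corpus(corp$passages, bundled_dictionaries())
  built <- build_document(events_to_statements(ext))
  tab <- document_statement_table(built$document)
  expect_equal(length(built$sidecar), nrow(tab))
  for (i in seq_along(built$sidecar)) {
    rec <- built$sidecar[[i]]
    expect_equal(rec$statement_index, i)
    expect_equal(rec$statement, tab$text[i])
    expect_true(length(rec$mentions) >= 1)
  }
  path <- tempfile(fileext = ".json")
  write_sidecar(built$sidecar, path)
  back <- read_sidecar(path)
  expect_equal(length(back), length(built$sidecar))
  expect_equal(back[[1]]$statement, built$sidecar[[1]]$statement)
})

test_that("document building is deterministic", {
  corp <- generate_corpus(generator_config(seed = 16, n_articles = 3))
  ext <- extract_corpus(corp$passages, bundled_dictionaries())
  a <- build_document(events_to_statements(ext))
  b <- build_document(events_to_statements(ext))
  expect_identical(write_bel_script(a$document), write_bel_script(b$document))
})

test_that("a statement without evidence is refused", {
  stmts <- tibble::tibble(
    pmid = "1", section = "results", sentence_id = 1L, start = 0L, end = 10L,
    sentence = NA_character_,
    statement = list(parse_statement(semi_auto_stmt)),
    mentions = list(NULL))
  expect_error(build_document(stmts), "evidence",
               class = "bel_conversion_error")
})

test_that("fragment assembly consumes two fragments and yields one statement", {
  doc <- tiny_document(c("p(HGNC:CYP4A11) ->", "-> bp(GOBP:angiogenesis)",
                         semi_auto_stmt))
  tab <- document_statement_table(doc)
  n_complete <- sum(tab$fragment_kind == "complete")
  n_frag <- sum(tab$fragment_kind != "complete")
  out <- apply_edits(doc, curation_edit("assemble_fragments", c(1, 2)))
  tab2 <- document_statement_table(out)
  expect_equal(sum(tab2$fragment_kind == "complete"), n_complete + 1)
  expect_equal(sum(tab2$fragment_kind != "complete"), n_frag - 2)
  expect_equal(tab2$text[1], semi_auto_stmt)
  # original untouched
  expect_equal(nrow(document_statement_table(doc)), 3)
})

test_that("assembly refuses mismatched relations or kinds", {
  doc <- tiny_document(c("p(HGNC:CYP4A11) ->", "-| bp(GOBP:angiogenesis)"))
  expect_error(apply_edits(doc, curation_edit("assemble_fragments", c(1, 2))),
               "disagree", class = "bel_edit_error")
  doc2 <- tiny_document(c("p(HGNC:CYP4A11) ->", "p(HGNC:MMP9) ->"))
  expect_error(apply_edits(doc2, curation_edit("assemble_fragments", c(1, 2))),
               class = "bel_edit_error")
})

test_that("modify_statement re-validates and refuses bad replacements", {
  doc <- tiny_document(semi_auto_stmt)
  out <- apply_edits(doc, curation_edit(
    "modify_statement", 1,
    "p(HGNC:CYP4A11) => bp(GOBP:'blood vessel development')"))
  expect_equal(document_statement_table(out)$relation, "directlyIncreases")
  expect_error(
    apply_edits(doc, curation_edit("modify_statement", 1, "q(HGNC:X) -> bp(GOBP:y)")),
    class = "bel_edit_error")
  expect_error(
    apply_edits(doc, curation_edit("modify_statement", 1,
                                   "kin(bp(GOBP:x)) -> bp(GOBP:y)")),
    class = "bel_edit_error")
  # the refused edits left the document unchanged
  expect_equal(document_statement_table(doc)$text, semi_auto_stmt)
})

test_that("reject removes statements; rejecting all empties the document", {
  doc <- tiny_document(c(semi_auto_stmt, manual_stmt))
  out <- apply_edits(doc, curation_edit("reject", c(1, 2)))
  expect_equal(nrow(document_statement_table(out)), 0)
  expect_equal(out$header$name, doc$header$name)
  expect_error(apply_edits(doc, curation_edit("reject", 99)),
               "out of range", class = "bel_edit_error")
})

test_that("set_annotation targets the enclosing block and checks the key", {
  doc <- tiny_document(semi_auto_stmt)
  out <- apply_edits(doc, curation_edit(
    "set_annotation", 1, list(key = "Tissue", value = "aorta")))
  expect_equal(out$blocks[[1]]$annotations$Tissue, "aorta")
  expect_error(apply_edits(doc, curation_edit(
    "set_annotation", 1, list(key = "Organ", value = "x"))),
    "not defined", class = "bel_edit_error")
})

test_that("edit scripts load from JSON lines", {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"kind":"reject","targets":[2]}',
    '{"kind":"set_annotation","targets":[1],"payload":{"key":"Cell","value":"macrophage"}}'),
    path)
  edits <- read_edit_script(path)
  expect_length(edits, 2)
  doc <- tiny_document(c(semi_auto_stmt, manual_stmt))
  out <- apply_edits(doc, edits)
  expect_equal(nrow(document_statement_table(out)), 1)
  expect_equal(out$blocks[[1]]$annotations$Cell, "macrophage")
})
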