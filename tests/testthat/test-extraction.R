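test_that("clean_text fixes hyphenation, line breaks and PDF artifacts", {
  expect_equal(clean_text("athero-\nsclerosis"), "atherosclerosis")
  expect_equal(clean_text("plaque\ndestabilization"), "plaque destabilization")
  # hand-built artifact table: ligatures, smart punctuation, controls
  artifacts <- c(
    "ﬁbrous cap"            = "fibrous cap",
    "inﬂammatory inﬁltrate" = "inflammatory infiltrate",
    "CHEBI:‘20-HETE’"       = "CHEBI:'20-HETE'",
    "“vulnerable” plaque"   = "\"vulnerable\" plaque",
    "ApoE−/− mice"          = "ApoE-/- mice",
    "tab\tseparated"        = "tab separated")
  for (raw in names(artifacts)) {
    expect_equal(clean_text(raw), unname(artifacts[raw]), info = raw)
  }
})

test_that("clean_text is idempotent", {
  raws <- c("athero-\nsclerosis and ‘20-HETE’ ﬂux", "already clean text.",
            "density per high-powered fields (HPF) (34.1 ± 7.3/HPF)")
  for (raw in raws) {
    once <- clean_text(raw)
    expect_equal(clean_text(once), once, info = raw)
  }
})

test_that("select_sections keeps abstract/methods/results in order", {
  p <- passage_table(pmid = rep("1", 4),
                     section = c("abstract", "introduction", "results",
                                 "discussion"),
                     text = paste("text", 1:4))
  kept <- select_sections(p)
  expect_equal(kept$section, c("abstract", "results"))
  expect_equal(kept$text, c("text 1", "text 3"))
})

test_that("articles with nothing retained produce a warning, not an error", {
  p <- passage_table(pmid = "9", section = "discussion", text = "x")
  expect_warning(out <- select_sections(p), "9")
  expect_equal(nrow(out), 0)
})

test_that("section filtering equals a brute-force filter on a random mix", {
  set.seed(5)
  sections <- sample(c("abstract", "methods", "results", "introduction",
                       "discussion", "conclusion", "other"), 40,
                     replace = TRUE)
  p <- passage_table(pmid = rep(sprintf("a%d", 1:8), each = 5),
                     section = sections, text = paste("t", 1:40))
  got <- suppressWarnings(select_sections(p))
  want <- p[p$section %in% c("abstract", "methods", "results"), ]
  expect_equal(got$text, want$text)
})

test_that("sentence segmentation splits on boundaries but not abbreviations", {
  p <- passage_table("1", "results", "CYP4A11 was induced. MMP9 increased.")
  sent <- segment_sentences(p)$sentences[[1]]
  expect_equal(nrow(sent), 2)
  expect_equal(sent$text, c("CYP4A11 was induced.", "MMP9 increased."))
  # spans are 0-based half-open into the passage text
  expect_equal(substr(p$text, sent$start[2] + 1, sent$end[2]), sent$text[2])

  tricky <- paste("capillary vessel counting showed that CYP4A11",
                  "transfection significantly increased microvessel density",
                  "per high-powered fields (HPF) (34.1 ± 7.3/HPF in control,",
                  "P < 0.05).")
  one <- segment_sentences(passage_table("2", "results", tricky))$sentences[[1]]
  expect_equal(nrow(one), 1)

  abbr <- "As shown by Smith et al. (2012), lesions grew. See Fig. 3 for details."
  two <- segment_sentences(passage_table("3", "results", abbr))$sentences[[1]]
  expect_equal(nrow(two), 2)
})

test_that("segmentation recovers every planted boundary in generated passages", {
  corp <- generate_corpus(generator_config(seed = 21, n_articles = 4,
                                           sentences_per_article = 15))
  seg <- segment_sentences(corp$passages)
  for (i in seq_len(nrow(seg))) {
    got <- seg$sentences[[i]][, c("start", "end", "text")]
    want <- corp$passages$sentences[[i]][, c("start", "end", "text")]
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("dictionary loading rejects synonym collisions", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tpreferred_name\tsynonyms\tnamespace",
               "A1\talpha\tshared name\tHGNC",
               "B2\tbeta\tshared name\tHGNC"), tsv)
  expect_error(read_dictionary(tsv), "collision",
               class = "bel_dictionary_error")
})

test_that("ner finds planted entities with longest-match resolution", {
  dicts <- bundled_dictionaries()
  m <- ner("CYP4A11 transfection significantly increased microvessel density",
           dicts)
  expect_equal(m$id, c("CYP4A11", "angiogenesis"))
  expect_equal(m$namespace, c("HGNC", "GOBP"))
  expect_equal(m$start, c(0L, 45L))
  # the surface form is kept while the id is normalized to the preferred one
  expect_equal(m$matched_text, c("CYP4A11", "microvessel density"))

  # overlapping candidates: the longer phrase wins over its sub-phrase
  m2 <- ner("a response to oxidative stress was observed", dicts)
  expect_equal(m2$id, "response to oxidative stress")
  expect_equal(nrow(m2), 1)

  expect_equal(nrow(ner("no entities here at all", dicts)), 0)
})

test_that("short tokens match case-sensitively, long ones case-insensitively", {
  dicts <- bundled_dictionaries()
  expect_equal(nrow(ner("the fas pathway", dicts)), 0)   # FAS is 3 chars
  expect_equal(ner("FAS signalling", dicts)$id, "FAS")
  expect_equal(ner("Cholesterol levels rose", dicts)$id, "cholesterol")
})

test_that("ner is deterministic and synonyms normalize to preferred ids", {
  dicts <- bundled_dictionaries()
  sent <- "oxLDL uptake enhanced foam cell formation"
  a <- ner(sent, dicts)
  b <- ner(sent, dicts)
  expect_identical(a, b)
  expect_true("oxidized low-density lipoprotein" %in% a$id)
})

test_that("adding a containing synonym never increases the mention count", {
  base <- bel_dictionary("GOBP", tibble::tibble(
    id = "cell adhesion", synonym = "cell adhesion"), bel_class = "process")
  ext <- bel_dictionary("GOBP", tibble::tibble(
    id = c("cell adhesion", "monocyte adhesion assay"),
    synonym = c("cell adhesion", "monocyte cell adhesion")),
    bel_class = "process")
  sent <- "monocyte cell adhesion was measured"
  expect_lte(nrow(ner(sent, list(ext))), nrow(ner(sent, list(base))))
})

test_that("events pair triggers with nearest cause and theme", {
  dicts <- bundled_dictionaries()
  sent <- "CYP4A11 transfection significantly increased angiogenesis"
  ev <- extract_events(sent, ner(sent, dicts))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "Positive_regulation")
  expect_equal(ev$cause_id, "CYP4A11")
  expect_equal(ev$theme_id, "angiogenesis")

  # theme-less trigger yields nothing
  expect_equal(nrow(extract_events("VEGFA increased",
                                   ner("VEGFA increased", dicts))), 0)

  # cause-less trigger yields an event without a cause
  sent2 <- "Treatment significantly increased angiogenesis"
  ev2 <- extract_events(sent2, ner(sent2, dicts))
  expect_equal(nrow(ev2), 1)
  expect_true(is.na(ev2$cause_id))
})

test_that("negated triggers are dropped by default and flagged on request", {
  dicts <- bundled_dictionaries()
  sent <- "CYP4A11 did not increase angiogenesis"
  men <- ner(sent, dicts)
  expect_equal(nrow(extract_events(sent, men)), 0)
  ev <- extract_events(sent, men, negation = "causesNoChange")
  expect_equal(ev$type, "No_regulation")
})

test_that("extracted events equal gold on the planted corpus", {
  corp <- generate_corpus(generator_config(seed = 33, n_articles = 5))
  dicts <- bundled_dictionaries()
  ext <- extract_corpus(segment_sentences(corp$passages), dicts)
  got <- list()
  for (i in seq_len(nrow(ext))) {
    ev <- ext$events[[i]]
    if (nrow(ev) == 0) next
    ev$sentence_key <- paste(ext$pmid[i], ext$sentence_id[i], sep = ":")
    got[[length(got) + 1]] <- ev[, c("sentence_key", "type", "cause_id",
                                     "theme_id")]
  }
  got <- dplyr::arrange(dplyr::bind_rows(got), sentence_key, theme_id)
  want <- dplyr::arrange(
    corp$gold_events[, c("sentence_key", "type", "cause_id", "theme_id")],
    sentence_key, theme_id)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("recall arithmetic matches its definition", {
  gold <- tibble::tibble(sentence_key = "s1", start = c(0L, 10L, 20L, 30L),
                         end = c(5L, 15L, 25L, 35L), namespace = "HGNC",
                         id = c("A", "B", "C", "D"))
  expect_equal(evaluate_recall(gold, gold)$recall_pct, c(100, 100))
  found <- rbind(gold[1:3, ],
                 tibble::tibble(sentence_key = "s1", start = c(40L, 50L),
                                end = c(45L, 55L), namespace = "HGNC",
                                id = c("X", "Y")))
  r <- evaluate_recall(found, gold)
  expect_equal(r$recall_pct[r$namespace == "HGNC"], 75)
  expect_equal(r$precision_pct[r$namespace == "HGNC"], 60)
  expect_error(evaluate_recall(found, gold, namespaces = "CHEBI"),
               "empty")
})

test_that("self-recall is 100 percent on arbitrary mention sets", {
  set.seed(12)
  corp <- generate_corpus(generator_config(seed = 12, n_articles = 3))
  r <- evaluate_recall(corp$gold_mentions, corp$gold_mentions)
  expect_true(all(r$recall_pct == 100))
})
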