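test_that("duplicate statements across documents merge into one edge", {
  d1 <- tiny_document(semi_auto_stmt, pmid = "111", name = "doc1")
  d2 <- tiny_document(semi_auto_stmt, pmid = "222", name = "doc2")
  k <- compile_kam(list(d1, d2))
  expect_equal(nrow(k$nodes), 2)
  expect_equal(nrow(k$edges), 1)
  expect_true(k$edges$causal)
  expect_equal(k$edges$evidence_count, 2L)
  expect_setequal(k$edges$evidence[[1]]$pmid, c("111", "222"))
})

test_that("the nested worked-example statement compiles to the documented structure", {
  k <- compile_kam(tiny_document(manual_stmt))
  expect_setequal(k$nodes$key,
                  c("p(HGNC:CYP4A11)", "sec(a(CHEBI:20-HETE))",
                    "a(CHEBI:20-HETE)", "bp(GOBP:'blood vessel development')"))
  causal <- k$edges[k$edges$causal, ]
  # inner edge, plus outer subject -> inner object with the outer relation
  expect_setequal(
    paste(causal$source, causal$target),
    c("sec(a(CHEBI:20-HETE)) bp(GOBP:'blood vessel development')",
      "p(HGNC:CYP4A11) bp(GOBP:'blood vessel development')"))
  noncausal <- k$edges[!k$edges$causal, ]
  expect_equal(paste(noncausal$source, noncausal$target, noncausal$relation),
               "sec(a(CHEBI:20-HETE)) a(CHEBI:20-HETE) hasComponent")
  expect_equal(noncausal$evidence_count, 0L)
  expect_true(noncausal$structural)
})

test_that("structural gene/RNA/protein and complex edges are inferred and switchable", {
  doc <- tiny_document(c(
    "g(HGNC:MMP9) -> bp(GOBP:angiogenesis)",
    "r(HGNC:MMP9) -> bp(GOBP:angiogenesis)",
    "p(HGNC:MMP9) -> bp(GOBP:angiogenesis)",
    "complex(p(HGNC:CD40LG), p(HGNC:CD40)) -> bp(GOBP:'T cell activation')"))
  k <- compile_kam(doc)
  keys <- kam_edge_keys(k, structural = TRUE)
  expect_true("g(HGNC:MMP9) r(HGNC:MMP9) transcribedTo" %in% keys)
  expect_true("r(HGNC:MMP9) p(HGNC:MMP9) translatedTo" %in% keys)
  expect_true(
    "complex(p(HGNC:CD40), p(HGNC:CD40LG)) p(HGNC:CD40) hasComponent" %in%
      keys ||
    "complex(p(HGNC:CD40LG), p(HGNC:CD40)) p(HGNC:CD40) hasComponent" %in%
      keys)
  k_off <- compile_kam(doc, infer = list(translated_to = FALSE,
                                         transcribed_to = FALSE,
                                         has_component = FALSE,
                                         wrapper = FALSE))
  expect_equal(sum(k_off$edges$structural), 0)
})

test_that("fragments do not compile and invalid documents are refused", {
  doc <- tiny_document(c(semi_auto_stmt, "p(HGNC:MMP9) ->"))
  k <- compile_kam(doc)
  expect_equal(nrow(k$edges), 1)
  bad <- bel_document(namespaces = c(HGNC = "-"),
                      blocks = list(bel_block(
                        bel_evidence("x"),
                        statements = list(parse_statement("p(HGNC:A) -> bp(GOBP:x)")))))
  expect_error(compile_kam(bad), class = "bel_validation_error")
})

test_that("compile equals the set-construction oracle on a generated corpus", {
  corp <- generate_bel_corpus(generator_config(seed = 19, n_articles = 6,
                                               statements_per_doc = 25,
                                               duplicate_rate = 0.3))
  k <- compile_kam(corp$docs, infer = list(has_component = FALSE,
                                           wrapper = FALSE,
                                           translated_to = FALSE,
                                           transcribed_to = FALSE))
  want <- oracle_compile(unique(corp$statements$text))
  expect_equal(sort(k$nodes$key), want$nodes)
  expect_equal(kam_edge_keys(k), want$edges)
  # evidence conservation: every (statement, evidence) pair lands on an edge
  expect_equal(sum(k$edges$evidence_count), nrow(corp$statements))
})

test_that("compile is independent of document order and merge is idempotent", {
  corp <- generate_bel_corpus(generator_config(seed = 23, n_articles = 5,
                                               statements_per_doc = 15,
                                               duplicate_rate = 0.2))
  k1 <- compile_kam(corp$docs)
  k2 <- compile_kam(rev(corp$docs))
  expect_equal(k1$nodes, k2$nodes)
  expect_equal(k1$edges, k2$edges)

  expect_equal(merge_kam(k1, k1)$edges, k1$edges)
  expect_equal(merge_kam(k1, empty_kam())$edges, k1$edges)
  expect_equal(merge_kam(k1, empty_kam())$nodes, k1$nodes)
})

test_that("merging disjoint models unions nodes and edges", {
  corp <- generate_bel_corpus(generator_config(seed = 29, n_articles = 4,
                                               statements_per_doc = 12))
  ka <- compile_kam(corp$docs[1:2])
  kb <- compile_kam(corp$docs[3:4])
  m <- merge_kam(ka, kb)
  expect_equal(sort(m$nodes$key), sort(union(ka$nodes$key, kb$nodes$key)))
  expect_equal(kam_edge_keys(m),
               sort(union(kam_edge_keys(ka), kam_edge_keys(kb))))
  km <- compile_kam(corp$docs)
  expect_equal(m$nodes, km$nodes)
  expect_equal(kam_edge_keys(m), kam_edge_keys(km))
})

test_that("censuses satisfy their conservation identities", {
  ec0 <- edge_census(empty_kam())
  expect_equal(ec0$causal + ec0$non_causal, 0)
  expect_equal(nrow(node_census(empty_kam())), 15)
  expect_equal(sum(node_census(empty_kam())$n), 0)

  corp <- generate_bel_corpus(generator_config(seed = 31, n_articles = 5,
                                               statements_per_doc = 20))
  k <- compile_kam(corp$docs)
  ec <- edge_census(k)
  expect_equal(ec$causal + ec$non_causal, nrow(k$edges))
  expect_equal(sum(ec$by_relation$n), nrow(k$edges))
  nc <- node_census(k)
  expect_equal(sum(nc$n), nrow(k$nodes))
  # oracle group-by over node functions
  want <- table(vapply(k$nodes$key, function(key) parse_term(key)$fn, ""))
  for (fn in names(want)) {
    expect_equal(nc$n[nc$fn == fn], unname(as.integer(want[fn])), info = fn)
  }
})

test_that("XGMML round-trips nodes, edges and attributes", {
  k <- compile_kam(tiny_document(c(semi_auto_stmt, manual_stmt,
                                   "p(HGNC:MMP9) -| bp(GOBP:angiogenesis)")))
  path <- tempfile(fileext = ".xgmml")
  export_xgmml(k, path)
  x <- xml2::read_xml(path)  # well-formed XML
  expect_equal(xml2::xml_name(xml2::xml_root(x)), "graph")
  back <- import_xgmml(path)
  expect_equal(back$nodes, k$nodes)
  expect_equal(back$edges[, c("source", "target", "relation", "causal",
                              "evidence_count")],
               k$edges[, c("source", "target", "relation", "causal",
                           "evidence_count")])
})

test_that("a 2-node model exports two node elements and one edge element", {
  k <- compile_kam(tiny_document(semi_auto_stmt))
  path <- tempfile(fileext = ".xgmml")
  export_xgmml(k, path)
  x <- xml2::read_xml(path)
  ns <- c(x = "http://www.cs.rpi.edu/XGMML")
  expect_length(xml2::xml_find_all(x, "./x:node", ns = ns), 2)
  expect_length(xml2::xml_find_all(x, "./x:edge", ns = ns), 1)
})

test_that("KAM JSON round-trips including evidence text", {
  corp <- generate_bel_corpus(generator_config(seed = 37, n_articles = 3,
                                               statements_per_doc = 8,
                                               duplicate_rate = 0.3))
  k <- compile_kam(corp$docs)
  path <- tempfile(fileext = ".json")
  kam_to_json(k, path)
  back <- kam_from_json(path)
  expect_equal(back$nodes, k$nodes)
  expect_equal(back$edges, k$edges)
  expect_equal(back$provenance, k$provenance)
})

test_that("self-edges are retained and counted once", {
  k <- compile_kam(tiny_document("bp(GOBP:angiogenesis) -> bp(GOBP:angiogenesis)"))
  expect_equal(nrow(k$edges), 1)
  expect_equal(edge_census(k)$causal, 1)
})
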