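star_kam <- function(n_leaves = 5) {
  stmts <- sprintf("p(HGNC:HUB) -> bp(GOBP:'process %d')", seq_len(n_leaves))
  doc <- bel_document(namespaces = c(HGNC = "-", GOBP = "-"),
                      blocks = lapply(stmts, function(s) {
                        bel_block(bel_evidence(s), statements = list(
                          parse_statement(s)))
                      }))
  compile_kam(doc)
}

ring_kam <- function(n = 6) {
  stmts <- sprintf("bp(GOBP:'n%d') -> bp(GOBP:'n%d')", seq_len(n),
                   c(seq_len(n)[-1], 1L))
  compile_kam(bel_document(namespaces = c(GOBP = "-"),
                           blocks = lapply(stmts, function(s)
                             bel_block(bel_evidence(s),
                                       statements = list(parse_statement(s))))))
}

test_that("degree report matches closed forms on a star", {
  k <- star_kam(5)
  rep <- degree_report(k)
  expect_equal(sort(rep$degrees$degree), c(1, 1, 1, 1, 1, 5))
  expect_equal(rep$mean_degree, 10 / 6)
  expect_equal(sum(rep$degrees$degree), 2 * rep$n_edges)
})

test_that("an isolated node has degree zero and mean zero", {
  k <- empty_kam()
  k$nodes <- tibble::tibble(key = "p(HGNC:X)", fn = "p", namespace = "HGNC",
                            value = "X")
  rep <- degree_report(k)
  expect_equal(rep$degrees$degree, 0L)
  expect_equal(rep$mean_degree, 0)
})

test_that("degree equals a brute-force adjacency count on a random graph", {
  k <- generate_graph(generator_config(seed = 41, graph_n = 500, graph_m = 2))
  rep <- degree_report(k)
  # oracle: count endpoint occurrences over the unique undirected edge set
  und <- unique(t(apply(cbind(k$edges$source, k$edges$target), 1, sort)))
  cnt <- table(c(und[, 1], und[, 2]))
  want <- as.integer(cnt[rep$degrees$node])
  want[is.na(want)] <- 0L
  expect_equal(rep$degrees$degree, want)
  expect_equal(sum(rep$degrees$degree), 2 * nrow(und))
})

test_that("multi-edge policy changes the projection", {
  d1 <- tiny_document(semi_auto_stmt, pmid = "1")
  d2 <- tiny_document("p(HGNC:CYP4A11) => bp(GOBP:angiogenesis)", pmid = "2")
  k <- compile_kam(list(d1, d2))  # two parallel edges, different relations
  expect_equal(degree_report(k, "simple")$n_edges, 1)
  expect_equal(degree_report(k, "multi")$n_edges, 2)
})

test_that("hubs are exactly the nodes above mean degree", {
  expect_equal(find_hubs(star_kam(5))$node, "p(HGNC:HUB)")
  expect_equal(nrow(find_hubs(ring_kam(6))), 0)  # regular graph: no hubs
  k <- generate_graph(generator_config(seed = 43, graph_n = 300, graph_m = 2))
  rep <- degree_report(k)
  hubs <- find_hubs(rep)
  want <- rep$degrees$node[rep$degrees$degree > mean(rep$degrees$degree)]
  expect_setequal(hubs$node, want)
  expect_true(all(hubs$degree > attr(hubs, "threshold")))
})

test_that("preferential-attachment graphs read as scale-free, uniform ones do not", {
  pa <- generate_graph(generator_config(seed = 47, graph_n = 2000,
                                        graph_m = 2))
  res <- scale_free_check(pa)
  expect_equal(res$verdict, "scale_free")
  expect_lt(res$exponent, -1)
  expect_gt(res$exponent, -4)

  verdicts <- vapply(1:20, function(i) {
    er <- generate_graph(generator_config(seed = 1000 + i, graph_n = 2000,
                                          graph_p = 0.01), mode = "uniform")
    scale_free_check(er)$verdict
  }, character(1))
  expect_gt(mean(verdicts == "not_scale_free"), 0.5)
})

test_that("a single-valued degree distribution is indeterminate", {
  expect_equal(scale_free_check(ring_kam(10))$verdict, "indeterminate")
})

test_that("network comparison is reflexive, null on empty, and symmetric", {
  k <- compile_kam(tiny_document(c(semi_auto_stmt, manual_stmt)))
  self <- compare_networks(k, k)
  expect_equal(self$shared_nodes, nrow(k$nodes))
  expect_equal(self$shared_edges, nrow(k$edges))
  expect_equal(self$shared_hubs, self$hubs_a)

  null <- compare_networks(k, empty_kam())
  expect_equal(null$shared_nodes, 0)
  expect_equal(null$shared_edges, 0)

  corp <- generate_bel_corpus(generator_config(seed = 53, n_articles = 6,
                                               statements_per_doc = 15,
                                               duplicate_rate = 0.2))
  ka <- compile_kam(corp$docs[1:4])
  kb <- compile_kam(corp$docs[3:6])
  ab <- compare_networks(ka, kb)
  ba <- compare_networks(kb, ka)
  expect_equal(ab$shared_nodes, ba$shared_nodes)
  expect_equal(ab$shared_edges, ba$shared_edges)
  expect_equal(ab$shared_nodes,
               length(intersect(ka$nodes$key, kb$nodes$key)))
  expect_equal(ab$shared_edges,
               length(intersect(kam_edge_keys(ka), kam_edge_keys(kb))))
  expect_lte(ab$shared_nodes, min(ab$nodes_a, ab$nodes_b))
})

test_that("evidence overlap follows set arithmetic", {
  s <- sprintf("Sentence number %d about plaques.", 1:15)
  expect_equal(evidence_overlap(s[1:10], s[1:10])$jaccard_pct, 100)
  expect_equal(evidence_overlap(s[1:5], s[6:10])$jaccard_pct, 0)
  r <- evidence_overlap(s[1:10], s[6:15])
  expect_equal(r$jaccard_pct, 100 * 5 / 15, tolerance = 1e-12)
  expect_equal(r$pct_of_a, 50)
  expect_equal(r$n_shared, 5)
  # normalization: case, punctuation and spacing do not matter
  r2 <- evidence_overlap("MMP9  increased, markedly.",
                         "mmp9 increased markedly")
  expect_equal(r2$jaccard_pct, 100)
})

test_that("curation metrics divide and round half-up to one decimal", {
  m <- curation_metrics(data.frame(arm = "a", minutes = 100,
                                   statements = 100, annotations = 0))
  expect_equal(m$min_per_statement, 1.0)
  expect_equal(m$min_per_statement_annotation, 1.0)
  # half-up at the boundary: 0.25 -> 0.3, where round() would give 0.2
  m2 <- curation_metrics(data.frame(arm = "b", minutes = 25,
                                    statements = 100, annotations = 0))
  expect_equal(m2$min_per_statement, 0.3)
  expect_error(curation_metrics(data.frame(arm = "c", minutes = 10,
                                           statements = 0, annotations = 0)),
               "statements > 0")
})
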