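# Shared test fixtures and independent oracles.

# the two worked-example annotations of the CYP4A11 evidence sentence
semi_auto_stmt <- "p(HGNC:CYP4A11) -> bp(GOBP:angiogenesis)"
manual_stmt <-
  "p(HGNC:CYP4A11) -> (sec(a(CHEBI:20-HETE)) -> bp(GOBP:'blood vessel development'))"

tiny_document <- function(statements = semi_auto_stmt,
                          pmid = "21120482",
                          name = "tiny",
                          annotations = list()) {
  blocks <- lapply(seq_along(statements), function(i) {
    bel_block(
      bel_evidence(sprintf("Evidence sentence %d.", i), pmid = pmid,
                   section = "results"),
      annotations = annotations,
      statements = list(parse_statement(statements[i])))
  })
  bel_document(name = name,
               namespaces = c(HGNC = "-", GOBP = "-", CHEBI = "-",
                              SCHEM = "-", MGI = "-"),
               blocks = blocks)
}

# independent set-construction oracle for the KAM compiler: nodes and
# statement edges derived from raw statement texts by brute-force set
# arithmetic over the parsed ASTs (no compile_kam() internals involved)
oracle_terms <- function(term) {
  out <- list(term)
  for (a in term$args) {
    if (inherits(a, "bel_term")) out <- c(out, oracle_terms(a))
  }
  out
}

oracle_compile <- function(statement_texts) {
  nodes <- character()
  edges <- character()
  for (txt in statement_texts) {
    s <- parse_statement(txt)
    if (s$fragment_kind != "complete") next
    terms <- oracle_terms(s$subject)
    if (inherits(s$object, "bel_statement")) {
      inner <- s$object
      terms <- c(terms, oracle_terms(inner$subject),
                 oracle_terms(inner$object))
      edges <- c(edges,
                 paste(serialize_term(inner$subject),
                       serialize_term(inner$object), inner$relation),
                 paste(serialize_term(s$subject),
                       serialize_term(inner$object), s$relation))
    } else {
      terms <- c(terms, oracle_terms(s$object))
      edges <- c(edges, paste(serialize_term(s$subject),
                              serialize_term(s$object), s$relation))
    }
    nodes <- c(nodes, vapply(terms, serialize_term, character(1L)))
  }
  list(nodes = sort(unique(nodes)), edges = sort(unique(edges)))
}

kam_edge_keys <- function(k, structural = NA) {
  e <- k$edges
  if (!is.na(structural)) e <- e[e$structural == structural, , drop = FALSE]
  sort(paste(e$source, e$target, e$relation))
}

# random statement generator for parser round-trip property tests,
# independent of the fixtures module's templates
random_nsv <- function() {
  ns <- sample(c("HGNC", "GOBP", "CHEBI", "MGI", "SCHEM"), 1L)
  val <- if (runif(1) < 0.3) {
    paste(sample(c("blood", "vessel", "20-HETE", "foam cell", "plaque",
                   "T cell"), 2L), collapse = " ")
  } else {
    paste0(sample(LETTERS, 1L),
           paste(sample(c(LETTERS, 0:9), sample(2:6, 1L), replace = TRUE),
                 collapse = ""))
  }
  bel_nsv(ns, val)
}

random_term <- function() {
  kind <- sample(c("simple", "group", "wrapper"), 1L,
                 prob = c(0.6, 0.15, 0.25))
  if (kind == "simple") {
    fn <- sample(c("a", "p", "r", "g", "bp", "path"), 1L)
    return(bel_term(fn, random_nsv()))
  }
  if (kind == "group") {
    fn <- sample(c("complex", "composite"), 1L)
    members <- lapply(seq_len(sample(2:3, 1L)), function(i) {
      bel_term(sample(c("a", "p", "r", "g"), 1L), random_nsv())
    })
    return(bel_term(fn, members))
  }
  fn <- sample(c("act", "pep", "kin", "cat", "tscript", "deg", "sec"), 1L)
  inner_fn <- sample(c("a", "p", "r", "g"), 1L)
  bel_term(fn, bel_term(inner_fn, random_nsv()))
}

random_statement <- function() {
  rel <- sample(bel_relations()$name, 1L)
  u <- runif(1)
  if (u < 0.1) return(bel_statement(random_term(), rel, NULL))
  if (u < 0.2) return(bel_statement(NULL, rel, random_term()))
  if (u < 0.35) {
    inner <- bel_statement(random_term(),
                           sample(bel_relations()$name, 1L), random_term())
    return(bel_statement(random_term(), rel, inner))
  }
  bel_statement(random_term(), rel, random_term())
}

statement_equal <- function(a, b) {
  identical(serialize_statement(a), serialize_statement(b)) &&
    identical(a$fragment_kind, b$fragment_kind)
}

document_equal <- function(a, b) {
  norm_ev <- function(ev) list(text = ev$text, pmid = ev$pmid,
                               section = ev$section, span = ev$span)
  sort_by_name <- function(x) {
    if (!length(x)) return(list())
    as.list(x)[order(names(x))]
  }
  norm <- function(d) {
    list(header = d$header,
         namespaces = sort_by_name(d$namespaces),
         annotations = sort_by_name(d$annotations),
         blocks = lapply(d$blocks, function(b) {
           list(evidence = norm_ev(b$evidence),
                annotations = sort_by_name(b$annotations),
                statements = vapply(b$statements, serialize_statement,
                                    character(1L)))
         }))
  }
  identical(norm(a), norm(b))
}
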