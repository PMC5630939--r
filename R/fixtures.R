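# Deterministic fixtures: synthetic annotated corpora with gold mentions,
# events and statements; synthetic BEL corpora with an independent statement
# table for set-based oracles; and random graphs (preferential-attachment /
# uniform) in KAM form so every analysis operation applies. Template-based
# generation keeps gold alignment exact: on the clean setting the rule-based
# pipeline recovers the gold annotations completely, so end-to-end tests
# have a known truth.

#' Generator configuration
#'
#' @param seed Integer seed; the same configuration always produces
#'   byte-identical outputs.
#' @param n_articles Number of synthetic articles.
#' @param sentences_per_article Sentences per article passage.
#' @param fragment_rate Fraction of sentences whose event lacks a cause
#'   (yielding statement fragments downstream).
#' @param distractor_rate Fraction of sentences with no planted entities.
#' @param duplicate_rate Cross-document duplicate-statement rate for the
#'   BEL-corpus generator.
#' @param withheld_rate Fraction of the entity pool whose synonyms are
#'   designated "withheld" for dictionary-ablation experiments (expected
#'   NER recall is then approximately `1 - withheld_rate`).
#' @param statements_per_doc Statements per document for the BEL-corpus
#'   generator.
#' @param graph_n,graph_m,graph_p Random-graph parameters: nodes, edges
#'   added per step (preferential attachment), edge probability (uniform).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_articles = 7L,
                             sentences_per_article = 12L,
                             fragment_rate = 0.1, distractor_rate = 0.15,
                             duplicate_rate = 0.1, withheld_rate = 0,
                             statements_per_doc = 10L,
                             graph_n = 500L, graph_m = 2L, graph_p = 0.01) {
  structure(list(seed = as.integer(seed), n_articles = as.integer(n_articles),
                 sentences_per_article = as.integer(sentences_per_article),
                 fragment_rate = fragment_rate,
                 distractor_rate = distractor_rate,
                 duplicate_rate = duplicate_rate,
                 withheld_rate = withheld_rate,
                 statements_per_doc = as.integer(statements_per_doc),
                 graph_n = as.integer(graph_n),
                 graph_m = as.integer(graph_m), graph_p = graph_p),
            class = "generator_config")
}

with_fixture_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

# templates: {A} cause slot (gene), {B} theme slot; `trigger` is the surface
# form planted in the sentence
.corpus_templates <- list(
  list(text = c("", " significantly increased ", "."),
       trigger = "increased", type = "Positive_regulation", cause = TRUE),
  list(text = c("", " markedly induced ", " in ApoE-deficient mice."),
       trigger = "induced", type = "Positive_regulation", cause = TRUE),
  list(text = c("", " promoted ", " in advanced lesions."),
       trigger = "promoted", type = "Positive_regulation", cause = TRUE),
  list(text = c("", " upregulated ", "."),
       trigger = "upregulated", type = "Positive_regulation", cause = TRUE),
  list(text = c("", " strongly enhanced ", "."),
       trigger = "enhanced", type = "Positive_regulation", cause = TRUE),
  list(text = c("", " inhibited ", "."),
       trigger = "inhibited", type = "Negative_regulation", cause = TRUE),
  list(text = c("", " treatment reduced ", " in plaques."),
       trigger = "reduced", type = "Negative_regulation", cause = TRUE),
  list(text = c("", " suppressed ", "."),
       trigger = "suppressed", type = "Negative_regulation", cause = TRUE),
  list(text = c("", " markedly decreased ", "."),
       trigger = "decreased", type = "Negative_regulation", cause = TRUE),
  list(text = c("", " downregulated ", " in the aortic arch."),
       trigger = "downregulated", type = "Negative_regulation", cause = TRUE)
)

.fragment_templates <- list(
  list(text = c("Treatment significantly increased ", "."),
       trigger = "increased", type = "Positive_regulation", cause = FALSE),
  list(text = c("Dietary intervention reduced ", "."),
       trigger = "reduced", type = "Negative_regulation", cause = FALSE)
)

.distractor_sentences <- c(
  "Plaque sections were stained and examined by light microscopy.",
  "Mice were fed a high-fat diet for twelve weeks.",
  "Lesion area was quantified by computer-assisted planimetry.",
  "Sections were analysed by two blinded observers."
)

.fixture_class_map <- c(gene_protein = "p", chemical = "a", process = "bp",
                        complex = "complex", family = "p")

fixture_statement_text <- function(rel_token, cause_ns, cause_id, cause_class,
                                   theme_ns, theme_id, theme_class) {
  quote_val <- function(v) {
    if (grepl("[^A-Za-z0-9_-]", v)) paste0("'", v, "'") else v
  }
  theme <- sprintf("%s(%s:%s)", .fixture_class_map[[theme_class]], theme_ns,
                   quote_val(theme_id))
  if (is.na(cause_id)) return(paste(rel_token, theme))
  cause <- sprintf("%s(%s:%s)", .fixture_class_map[[cause_class]], cause_ns,
                   quote_val(cause_id))
  paste(cause, rel_token, theme)
}

#' Generate a synthetic annotated corpus
#'
#' Builds templated sentences with planted entities (sampled from the
#' supplied dictionaries) and regulation triggers, together with the gold
#' mentions, events and statements those plants imply. Sentence offsets and
#' mention spans are exact by construction. With a positive
#' `withheld_rate`, a fixed subset of the entity pool is designated
#' withheld (returned in `$withheld`); dropping those synonyms from the
#' dictionaries with [drop_synonyms()] emulates an incomplete vocabulary.
#'
#' @param cfg A [generator_config()].
#' @param dictionaries Named list of dictionaries (default: the bundled
#'   excerpts). The first gene_protein dictionary supplies causes; themes
#'   are drawn from the process and chemical dictionaries.
#' @return A list: `passages` (segmented passage tibble), `gold_mentions`,
#'   `gold_events`, `gold_statements` (tibbles), `withheld` (tibble of
#'   withheld entities) and `config`.
#' @export
generate_corpus <- function(cfg = generator_config(),
                            dictionaries = bundled_dictionaries()) {
  stopifnot(inherits(cfg, "generator_config"))
  classes <- vapply(dictionaries, function(d) d$bel_class, character(1L))
  cause_dict <- dictionaries[[which(classes == "gene_protein")[1L]]]
  theme_dicts <- dictionaries[classes %in% c("process", "chemical")]
  if (is.null(cause_dict) || !length(theme_dicts)) {
    abort("generate_corpus needs a gene_protein and a process/chemical dictionary")
  }
  pools <- lapply(c(list(cause = cause_dict), unname(theme_dicts)),
                  function(d) {
    pref <- d$entries[!duplicated(d$entries$id), , drop = FALSE]
    tibble(namespace = d$namespace, id = pref$id, surface = pref$synonym,
           bel_class = d$bel_class)
  })
  cause_pool <- pools[[1L]]
  theme_pool <- bind_rows(pools[-1L])

  with_fixture_seed(cfg$seed, {
    withheld <- bind_rows(
      cause_pool[sample.int(nrow(cause_pool),
                            round(cfg$withheld_rate * nrow(cause_pool))), ],
      theme_pool[sample.int(nrow(theme_pool),
                            round(cfg$withheld_rate * nrow(theme_pool))), ])
    mention_rows <- list(); event_rows <- list(); stmt_rows <- list()
    passage_rows <- list()
    for (a in seq_len(cfg$n_articles)) {
      pmid <- sprintf("90%05d", a)
      sents <- character(cfg$sentences_per_article)
      sent_meta <- list()
      for (s in seq_len(cfg$sentences_per_article)) {
        u <- stats::runif(1L)
        if (u < cfg$distractor_rate) {
          sents[s] <- sample(.distractor_sentences, 1L)
          next
        }
        is_frag <- u < cfg$distractor_rate + cfg$fragment_rate
        tpl <- if (is_frag) {
          .fragment_templates[[sample.int(length(.fragment_templates), 1L)]]
        } else {
          .corpus_templates[[sample.int(length(.corpus_templates), 1L)]]
        }
        theme <- theme_pool[sample.int(nrow(theme_pool), 1L), ]
        cause <- if (tpl$cause) cause_pool[sample.int(nrow(cause_pool), 1L), ]
        parts <- tpl$text
        if (tpl$cause) {
          text <- paste0(parts[1L], cause$surface, parts[2L], theme$surface,
                         parts[3L])
          cause_start <- nchar(parts[1L])
          cause_end <- cause_start + nchar(cause$surface)
          theme_start <- cause_end + nchar(parts[2L])
        } else {
          text <- paste0(parts[1L], theme$surface, parts[2L])
          cause_start <- NA_integer_; cause_end <- NA_integer_
          theme_start <- nchar(parts[1L])
        }
        theme_end <- theme_start + nchar(theme$surface)
        trig_at <- regexpr(tpl$trigger, text, fixed = TRUE)
        sents[s] <- text
        sent_meta[[length(sent_meta) + 1L]] <- list(
          sid = s, tpl = tpl, cause = cause, theme = theme,
          cause_start = cause_start, cause_end = cause_end,
          theme_start = theme_start, theme_end = theme_end,
          trig_start = as.integer(trig_at) - 1L,
          trig_end = as.integer(trig_at) + attr(trig_at, "match.length") - 1L)
      }
      text <- paste(sents, collapse = " ")
      offs <- cumsum(c(0L, utils::head(nchar(sents) + 1L, -1L)))
      passage_rows[[a]] <- tibble(
        pmid = pmid, section = "results", text = text,
        sentences = list(tibble(sentence_id = seq_along(sents),
                                start = offs, end = offs + nchar(sents),
                                text = sents)))
      for (m in sent_meta) {
        skey <- paste(pmid, m$sid, sep = ":")
        if (!is.null(m$cause)) {
          mention_rows[[length(mention_rows) + 1L]] <- tibble(
            pmid = pmid, sentence_id = m$sid, sentence_key = skey,
            start = m$cause_start, end = m$cause_end,
            matched_text = m$cause$surface, namespace = m$cause$namespace,
            id = m$cause$id, bel_class = m$cause$bel_class)
        }
        mention_rows[[length(mention_rows) + 1L]] <- tibble(
          pmid = pmid, sentence_id = m$sid, sentence_key = skey,
          start = m$theme_start, end = m$theme_end,
          matched_text = m$theme$surface, namespace = m$theme$namespace,
          id = m$theme$id, bel_class = m$theme$bel_class)
        event_rows[[length(event_rows) + 1L]] <- tibble(
          pmid = pmid, sentence_id = m$sid, sentence_key = skey,
          type = m$tpl$type, trigger = m$tpl$trigger,
          trigger_start = m$trig_start, trigger_end = m$trig_end,
          cause_namespace = if (is.null(m$cause)) NA_character_ else
            m$cause$namespace,
          cause_id = if (is.null(m$cause)) NA_character_ else m$cause$id,
          cause_class = if (is.null(m$cause)) NA_character_ else
            m$cause$bel_class,
          theme_namespace = m$theme$namespace, theme_id = m$theme$id,
          theme_class = m$theme$bel_class)
        rel_token <- switch(m$tpl$type, Positive_regulation = "->",
                            Negative_regulation = "-|")
        stmt_rows[[length(stmt_rows) + 1L]] <- tibble(
          pmid = pmid, sentence_id = m$sid, sentence_key = skey,
          text = fixture_statement_text(
            rel_token,
            if (is.null(m$cause)) NA_character_ else m$cause$namespace,
            if (is.null(m$cause)) NA_character_ else m$cause$id,
            if (is.null(m$cause)) NA_character_ else m$cause$bel_class,
            m$theme$namespace, m$theme$id, m$theme$bel_class))
      }
    }
    list(passages = bind_rows(passage_rows),
         gold_mentions = if (length(mention_rows)) bind_rows(mention_rows)
           else tibble(),
         gold_events = if (length(event_rows)) bind_rows(event_rows)
           else tibble(),
         gold_statements = if (length(stmt_rows)) bind_rows(stmt_rows)
           else tibble(),
         withheld = withheld, config = cfg)
  })
}

#' Remove designated synonyms from dictionaries
#'
#' @param dictionaries Named list of `bel_dictionary` objects.
#' @param withheld Tibble with columns `namespace`, `id` (e.g. the
#'   `$withheld` element of [generate_corpus()]); every synonym of the
#'   listed identifiers is removed from the matching dictionary.
#' @return The ablated dictionary list.
#' @export
drop_synonyms <- function(dictionaries, withheld) {
  lapply(dictionaries, function(d) {
    drop_ids <- withheld$id[withheld$namespace == d$namespace]
    if (!length(drop_ids)) return(d)
    entries <- d$entries[!d$entries$id %in% drop_ids, , drop = FALSE]
    bel_dictionary(d$namespace, entries, bel_class = d$bel_class,
                   case_policy = d$case_policy)
  })
}

#' Generate a synthetic BEL corpus
#'
#' Documents draw their statements from a shared pool, so a positive
#' `duplicate_rate` makes the same statement appear in several documents
#' (merging into one KAM edge with accumulated evidence). The returned
#' statement table is the input to independent set-based oracles for the
#' compiler.
#'
#' @param cfg A [generator_config()].
#' @param dictionaries Dictionaries supplying entity identifiers.
#' @return A list: `docs` (list of [bel_document()]), `statements` (tibble
#'   `doc`, `pmid`, `text`, `evidence`), `config`.
#' @export
generate_bel_corpus <- function(cfg = generator_config(),
                                dictionaries = bundled_dictionaries()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_articles == 0L) {
    return(list(docs = list(), statements = tibble(), config = cfg))
  }
  classes <- vapply(dictionaries, function(d) d$bel_class, character(1L))
  gene <- dictionaries[[which(classes == "gene_protein")[1L]]]
  proc <- dictionaries[[which(classes == "process")[1L]]]
  chem <- dictionaries[[which(classes == "chemical")[1L]]]
  gids <- unique(gene$entries$id)
  pids <- unique(proc$entries$id)
  cids <- unique(chem$entries$id)
  quote_val <- function(v) {
    ifelse(grepl("[^A-Za-z0-9_-]", v), paste0("'", v, "'"), v)
  }
  with_fixture_seed(cfg$seed + 1L, {
    n_total <- cfg$n_articles * cfg$statements_per_doc
    pool_size <- max(2L, ceiling(n_total * (1 - cfg$duplicate_rate)))
    pool <- vapply(seq_len(pool_size), function(i) {
      subj <- sprintf("p(%s:%s)", gene$namespace,
                      quote_val(sample(gids, 1L)))
      rel <- sample(c("->", "-|", "=>", "=|"), 1L,
                    prob = c(0.5, 0.3, 0.1, 0.1))
      obj <- if (stats::runif(1L) < 0.6) {
        sprintf("bp(%s:%s)", proc$namespace, quote_val(sample(pids, 1L)))
      } else {
        sprintf("a(%s:%s)", chem$namespace, quote_val(sample(cids, 1L)))
      }
      paste(subj, rel, obj)
    }, character(1L))
    pool <- unique(pool)
    ns_decl <- stats::setNames(rep("-", 3L),
                               c(gene$namespace, proc$namespace,
                                 chem$namespace))
    docs <- list()
    stmt_rows <- list()
    for (dnum in seq_len(cfg$n_articles)) {
      pmid <- sprintf("80%05d", dnum)
      doc_name <- sprintf("synthetic-%02d", dnum)
      picks <- sample(pool, cfg$statements_per_doc, replace = TRUE)
      picks <- unique(picks)  # within a document a statement appears once
      blocks <- lapply(seq_along(picks), function(i) {
        ev <- bel_evidence(sprintf("Synthetic evidence %d for %s.", i,
                                   picks[i]),
                           pmid = pmid, section = "results")
        bel_block(ev, statements = list(parse_statement(picks[i])))
      })
      docs[[dnum]] <- bel_document(name = doc_name,
                                   namespaces = ns_decl, blocks = blocks)
      stmt_rows[[dnum]] <- tibble(
        doc = doc_name, pmid = pmid, text = picks,
        evidence = vapply(blocks, function(b) b$evidence$text,
                          character(1L)))
    }
    list(docs = docs, statements = bind_rows(stmt_rows), config = cfg)
  })
}

#' Generate a random graph in KAM form
#'
#' Preferential-attachment (Barabasi-Albert, the positive control for
#' scale-free topology) or uniform (Erdos-Renyi) random graphs, returned as
#' a `kam` so every analysis operation applies directly.
#'
#' @param cfg A [generator_config()] (uses `graph_n`, `graph_m`, `graph_p`).
#' @param mode `"preferential_attachment"` or `"uniform"`.
#' @return A `kam` whose nodes are synthetic protein terms.
#' @export
generate_graph <- function(cfg = generator_config(),
                           mode = c("preferential_attachment", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "generator_config"))
  with_fixture_seed(cfg$seed + 2L, {
    g <- if (mode == "preferential_attachment") {
      igraph::sample_pa(cfg$graph_n, m = cfg$graph_m, directed = FALSE)
    } else {
      igraph::sample_gnp(cfg$graph_n, cfg$graph_p, directed = FALSE)
    }
    keys <- sprintf("p(SYN:N%05d)", seq_len(igraph::vcount(g)))
    nodes <- tibble(key = keys, fn = "p", namespace = "SYN",
                    value = sprintf("N%05d", seq_len(igraph::vcount(g))))
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- if (nrow(el)) {
      tibble(source = keys[el[, 1L]], target = keys[el[, 2L]],
             relation = "increases", causal = TRUE, structural = FALSE,
             evidence = rep(list(tibble(doc = character(),
                                        pmid = character(),
                                        sentence = character())),
                            nrow(el)),
             evidence_count = 0L)
    } else empty_kam_edges()
    new_kam(nodes, edges, provenance = paste0("synthetic-", mode))
  })
}
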