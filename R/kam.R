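# Knowledge assembly model (KAM): a directed multigraph over canonical BEL
# terms, compiled from validated BEL documents. Statement relations become
# edges keyed by (source, target, relation); duplicate statements merge into
# one edge accumulating evidence. Non-causal structural edges (gene->RNA->
# protein, complex->component, wrapper->inner abundance) are inferred so the
# network connects alternative forms of one entity even when every source
# statement is causal.

empty_kam_edges <- function() {
  tibble(source = character(), target = character(), relation = character(),
         causal = logical(), structural = logical(),
         evidence = list(), evidence_count = integer())
}

empty_kam_nodes <- function() {
  tibble(key = character(), fn = character(), namespace = character(),
         value = character())
}

new_kam <- function(nodes, edges, provenance = character()) {
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "kam")
}

#' An empty knowledge assembly model
#' @return A `kam` with no nodes or edges.
#' @export
empty_kam <- function() new_kam(empty_kam_nodes(), empty_kam_edges())

#' @export
print.kam <- function(x, ...) {
  cat("<kam> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      sum(x$edges$causal), " causal, ", sum(!x$edges$causal),
      " non-causal); ", length(x$provenance), " source document(s)\n",
      sep = "")
  invisible(x)
}

innermost_nsv <- function(term) {
  # namespace value of the innermost abundance/process; NA for multi-member
  # group terms
  if (length(term$args) == 1L) {
    a <- term$args[[1L]]
    if (inherits(a, "bel_nsv")) return(a)
    return(innermost_nsv(a))
  }
  NULL
}

node_row <- function(term) {
  nsv <- innermost_nsv(term)
  tibble(key = serialize_term(term), fn = term$fn,
         namespace = if (is.null(nsv)) NA_character_ else nsv$namespace,
         value = if (is.null(nsv)) NA_character_ else nsv$value)
}

collect_terms <- function(term) {
  # a term plus every inner term that becomes its own node: wrapper inners
  # and complex/composite members
  out <- list(term)
  for (a in term$args) {
    if (inherits(a, "bel_term")) out <- c(out, collect_terms(a))
  }
  out
}

evidence_row <- function(doc_id, ev) {
  tibble(doc = doc_id, pmid = ev$pmid, sentence = ev$text)
}

#' Compile BEL documents into a knowledge assembly model
#'
#' Every distinct canonical term (including wrapper inner terms and complex
#' members) becomes one node; nodes from different documents unify by key.
#' Complete statements become causal or non-causal edges according to their
#' relation; duplicate statements merge into one edge whose evidence
#' accumulates. A nested-object statement `A rel (B rel2 C)` produces the
#' inner statement's own edge `B rel2 C` and an edge from the outer subject
#' to the inner object, `A rel C`. Structural non-causal edges are then
#' inferred (each rule independently switchable): `complex -> member`
#' (hasComponent), wrapper term -> inner abundance (hasComponent),
#' `r(X) -> p(X)` (translatedTo) and `g(X) -> r(X)` (transcribedTo) whenever
#' both forms of the same namespace:value are present. Fragments do not
#' compile. The result is independent of document order.
#'
#' @param docs A [bel_document()] or list of them.
#' @param infer Named logical toggles for the structural-edge rules:
#'   `has_component`, `wrapper`, `translated_to`, `transcribed_to`
#'   (all `TRUE` by default).
#' @return An object of class `kam`: `nodes` and `edges` tibbles plus the
#'   provenance of source documents.
#' @export
#' @examples
#' doc <- read_bel_script(paste(
#'   'DEFINE NAMESPACE HGNC AS URL "-"',
#'   'DEFINE NAMESPACE GOBP AS URL "-"',
#'   'SET Evidence = "CYP4A11 increased angiogenesis."',
#'   "p(HGNC:CYP4A11) -> bp(GOBP:angiogenesis)", sep = "\n"))
#' compile_kam(doc)
compile_kam <- function(docs, infer = list()) {
  if (inherits(docs, "bel_document")) docs <- list(docs)
  infer_default <- list(has_component = TRUE, wrapper = TRUE,
                        translated_to = TRUE, transcribed_to = TRUE)
  infer <- utils::modifyList(infer_default, as.list(infer))
  for (d in docs) {
    v <- validate_document(d)
    if (nrow(v)) {
      abort(paste0("cannot compile, document '", d$header$name,
                   "' has violations: ", v$message[1L]),
            class = "bel_validation_error", violations = v)
    }
  }
  node_rows <- list()
  edge_rows <- list()
  add_edge <- function(src, tgt, rel, ev) {
    edge_rows[[length(edge_rows) + 1L]] <<- list(
      source = serialize_term(src), target = serialize_term(tgt),
      relation = rel, ev = ev)
  }
  for (d in docs) {
    doc_id <- d$header$name
    for (blk in d$blocks) {
      for (s in blk$statements) {
        if (s$fragment_kind != "complete") next
        ev <- evidence_row(doc_id, blk$evidence)
        terms <- collect_terms(s$subject)
        if (inherits(s$object, "bel_statement")) {
          inner <- s$object
          terms <- c(terms, collect_terms(inner$subject),
                     collect_terms(inner$object))
          add_edge(inner$subject, inner$object, inner$relation, ev)
          # outer relation connects the outer subject to the inner object
          # (the downstream entity the nested annotation is about)
          add_edge(s$subject, inner$object, s$relation, ev)
        } else {
          terms <- c(terms, collect_terms(s$object))
          add_edge(s$subject, s$object, s$relation, ev)
        }
        node_rows <- c(node_rows, lapply(terms, node_row))
      }
    }
  }
  nodes <- if (length(node_rows)) {
    distinct(bind_rows(node_rows))
  } else empty_kam_nodes()
  nodes <- nodes[order(nodes$key), , drop = FALSE]

  edges <- merge_edge_rows(edge_rows)

  # structural non-causal edges among the realized nodes
  node_terms <- lapply(nodes$key, parse_term)
  struct <- list()
  add_struct <- function(src_key, tgt_key, rel) {
    struct[[length(struct) + 1L]] <<- tibble(
      source = src_key, target = tgt_key, relation = rel)
  }
  for (t in node_terms) {
    cls <- fn_class(t$fn)
    key <- serialize_term(t)
    if (cls == "group" && infer$has_component) {
      for (a in t$args) {
        if (inherits(a, "bel_term")) {
          add_struct(key, serialize_term(a), "hasComponent")
        }
      }
    }
    if (cls == "wrapper" && infer$wrapper) {
      add_struct(key, serialize_term(t$args[[1L]]), "hasComponent")
    }
  }
  simple_keys <- function(fn) {
    sel <- nodes$fn == fn & !is.na(nodes$namespace)
    stats::setNames(nodes$key[sel],
                    paste(nodes$namespace[sel], nodes$value[sel]))
  }
  if (infer$translated_to || infer$transcribed_to) {
    gs <- simple_keys("g"); rs <- simple_keys("r"); ps <- simple_keys("p")
    if (infer$translated_to) {
      for (nv in intersect(names(rs), names(ps))) {
        add_struct(rs[[nv]], ps[[nv]], "translatedTo")
      }
    }
    if (infer$transcribed_to) {
      for (nv in intersect(names(gs), names(rs))) {
        add_struct(gs[[nv]], rs[[nv]], "transcribedTo")
      }
    }
  }
  if (length(struct)) {
    struct <- distinct(bind_rows(struct))
    # a statement-derived edge with the same key wins over an inferred one
    struct <- anti_join(struct, edges,
                        by = c("source", "target", "relation"))
    struct$causal <- FALSE
    struct$structural <- TRUE
    struct$evidence <- rep(list(tibble(doc = character(),
                                       pmid = character(),
                                       sentence = character())),
                           nrow(struct))
    struct$evidence_count <- 0L
    edges <- bind_rows(edges, struct)
  }
  edges <- edges[order(edges$source, edges$target, edges$relation), ,
                 drop = FALSE]
  prov <- sort(unique(vapply(docs, function(d) d$header$name,
                             character(1L))))
  new_kam(nodes, edges, prov)
}

merge_edge_rows <- function(edge_rows) {
  if (!length(edge_rows)) return(empty_kam_edges())
  keys <- vapply(edge_rows, function(e)
    paste(e$source, e$target, e$relation, sep = "\r"), character(1L))
  out <- list()
  for (k in unique(keys)) {
    grp <- edge_rows[keys == k]
    ev <- distinct(bind_rows(lapply(grp, function(e) e$ev)))
    ev <- ev[order(ev$doc, ev$pmid, ev$sentence), , drop = FALSE]
    e1 <- grp[[1L]]
    out[[length(out) + 1L]] <- tibble(
      source = e1$source, target = e1$target, relation = e1$relation,
      causal = relation_is_causal(e1$relation), structural = FALSE,
      evidence = list(ev), evidence_count = nrow(ev))
  }
  edges <- bind_rows(out)
  edges[order(edges$source, edges$target, edges$relation), , drop = FALSE]
}

#' Merge knowledge assembly models
#'
#' Node keys unify; edges union by (source, target, relation) with evidence
#' concatenated and de-duplicated. Idempotent: `merge_kam(K, K)` equals `K`;
#' the empty model is the identity.
#'
#' @param ... `kam` objects (or a single list of them).
#' @return The merged `kam`.
#' @export
merge_kam <- function(...) {
  kams <- list(...)
  if (length(kams) == 1L && !inherits(kams[[1L]], "kam")) kams <- kams[[1L]]
  stopifnot(all(vapply(kams, inherits, TRUE, what = "kam")))
  if (!length(kams)) return(empty_kam())
  nodes <- distinct(bind_rows(lapply(kams, function(k) k$nodes)))
  nodes <- nodes[order(nodes$key), , drop = FALSE]
  all_edges <- bind_rows(lapply(kams, function(k) k$edges))
  if (nrow(all_edges) == 0L) {
    return(new_kam(nodes, empty_kam_edges(),
                   sort(unique(unlist(lapply(kams, function(k)
                     k$provenance))))))
  }
  keys <- paste(all_edges$source, all_edges$target, all_edges$relation,
                sep = "\r")
  out <- list()
  for (k in unique(keys)) {
    grp <- all_edges[keys == k, , drop = FALSE]
    ev <- distinct(bind_rows(grp$evidence))
    if (nrow(ev)) ev <- ev[order(ev$doc, ev$pmid, ev$sentence), ,
                           drop = FALSE]
    out[[length(out) + 1L]] <- tibble(
      source = grp$source[1L], target = grp$target[1L],
      relation = grp$relation[1L], causal = grp$causal[1L],
      structural = all(grp$structural),
      evidence = list(ev),
      evidence_count = max(nrow(ev), max(grp$evidence_count)))
  }
  edges <- bind_rows(out)
  edges <- edges[order(edges$source, edges$target, edges$relation), ,
                 drop = FALSE]
  new_kam(nodes, edges,
          sort(unique(unlist(lapply(kams, function(k) k$provenance)))))
}

#' Edge census of a knowledge assembly model
#'
#' @param k A `kam`.
#' @return A list with `causal` and `non_causal` edge counts, `total`
#'   (their sum, equal to the number of edges by construction) and
#'   `by_relation`, a tibble of counts per relation.
#' @export
edge_census <- function(k) {
  stopifnot(inherits(k, "kam"))
  by_rel <- count(k$edges, .data$relation, name = "n")
  list(causal = sum(k$edges$causal),
       non_causal = sum(!k$edges$causal),
       total = nrow(k$edges),
       by_relation = by_rel)
}

#' Node census by BEL function
#'
#' @param k A `kam`.
#' @return A 15-row tibble (`fn`, `long`, `n`), one row per BEL term
#'   function in grammar order; counts sum to the node count.
#' @export
node_census <- function(k) {
  stopifnot(inherits(k, "kam"))
  counts <- table(factor(k$nodes$fn, levels = .bel_functions$short))
  tibble(fn = .bel_functions$short, long = .bel_functions$long,
         n = as.integer(counts[.bel_functions$short]))
}

#' Convert a KAM to an igraph graph
#'
#' @param k A `kam`.
#' @param directed Keep edge direction (default `TRUE`).
#' @return An `igraph` graph whose vertex names are the canonical term keys
#'   and whose edges carry `relation`, `causal` and `evidence_count`.
#' @export
kam_to_igraph <- function(k, directed = TRUE) {
  stopifnot(inherits(k, "kam"))
  igraph::graph_from_data_frame(
    d = k$edges[, c("source", "target", "relation", "causal",
                    "evidence_count")],
    directed = directed,
    vertices = data.frame(name = k$nodes$key, fn = k$nodes$fn,
                          stringsAsFactors = FALSE))
}

#' Serialize a KAM to / from JSON
#'
#' A plain JSON graph form (nodes, edges with flattened evidence) used for
#' pipeline artifacts and tests.
#'
#' @param k A `kam`.
#' @param path File path.
#' @return `kam_from_json()` returns the `kam`.
#' @export
kam_to_json <- function(k, path) {
  stopifnot(inherits(k, "kam"))
  edge_rows <- lapply(seq_len(nrow(k$edges)), function(i) {
    ev <- k$edges$evidence[[i]]
    list(source = k$edges$source[i], target = k$edges$target[i],
         relation = k$edges$relation[i], causal = k$edges$causal[i],
         structural = k$edges$structural[i],
         evidence_count = k$edges$evidence_count[i],
         evidence = list(doc = as.list(ev$doc), pmid = as.list(ev$pmid),
                         sentence = as.list(ev$sentence)))
  })
  obj <- list(nodes = list(key = as.list(k$nodes$key),
                           fn = as.list(k$nodes$fn),
                           namespace = as.list(k$nodes$namespace),
                           value = as.list(k$nodes$value)),
              edges = edge_rows,
              provenance = as.list(k$provenance))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname kam_to_json
#' @export
kam_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) {
    vapply(x, function(v) if (is.null(v)) NA_character_ else
      as.character(v), character(1L))
  }
  nodes <- tibble(key = chr(obj$nodes$key), fn = chr(obj$nodes$fn),
                  namespace = chr(obj$nodes$namespace),
                  value = chr(obj$nodes$value))
  edge_rows <- obj$edges
  if (length(edge_rows)) {
    edges <- bind_rows(lapply(edge_rows, function(e) {
      tibble(source = e$source, target = e$target, relation = e$relation,
             causal = isTRUE(e$causal), structural = isTRUE(e$structural),
             evidence = list(tibble(doc = chr(e$evidence$doc),
                                    pmid = chr(e$evidence$pmid),
                                    sentence = chr(e$evidence$sentence))),
             evidence_count = as.integer(e$evidence_count))
    }))
  } else {
    edges <- empty_kam_edges()
  }
  new_kam(nodes, edges, chr(obj$provenance))
}
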