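# Topology (degree, hubs, scale-free fit), network comparison, evidence
# overlap and curation-efficiency metrics. Degree follows the Cytoscape
# Network Analyzer convention by default: the undirected simple-graph
# projection (parallel edges collapsed); directed and multigraph modes are
# available behind the mode/directed arguments.

analysis_graph <- function(k, multi_edge_policy = c("simple", "multi"),
                           directed = FALSE) {
  multi_edge_policy <- match.arg(multi_edge_policy)
  g <- if (inherits(k, "igraph")) k else kam_to_igraph(k, directed = TRUE)
  if (!directed) g <- igraph::as_undirected(g, mode = "each")
  if (multi_edge_policy == "simple") {
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE,
                          edge.attr.comb = "ignore")
  }
  g
}

#' Degree report for a network
#'
#' @param k A `kam` or an `igraph` graph.
#' @param multi_edge_policy `"simple"` (default: parallel edges collapsed)
#'   or `"multi"` (every edge counts).
#' @param directed Compute in/out degree on the directed graph as well
#'   (total degree is always reported on the undirected view).
#' @return An object of class `degree_report`: a list with `degrees`
#'   (tibble `node`, `degree`, and `in_degree`/`out_degree` when directed),
#'   `histogram` (tibble `degree`, `n`) and `mean_degree`. The handshake
#'   identity holds: the degrees sum to twice the number of (projected)
#'   edges.
#' @export
degree_report <- function(k, multi_edge_policy = c("simple", "multi"),
                          directed = FALSE) {
  multi_edge_policy <- match.arg(multi_edge_policy)
  gu <- analysis_graph(k, multi_edge_policy, directed = FALSE)
  deg <- igraph::degree(gu, loops = TRUE)
  degrees <- tibble(node = names(deg) %||% as.character(seq_along(deg)),
                    degree = as.integer(deg))
  if (directed) {
    gd <- analysis_graph(k, multi_edge_policy, directed = TRUE)
    degrees$in_degree <- as.integer(igraph::degree(gd, mode = "in"))
    degrees$out_degree <- as.integer(igraph::degree(gd, mode = "out"))
  }
  hist <- count(degrees, .data$degree, name = "n")
  structure(
    list(degrees = degrees, histogram = hist,
         mean_degree = if (nrow(degrees)) mean(degrees$degree) else 0,
         n_edges = igraph::ecount(gu),
         multi_edge_policy = multi_edge_policy),
    class = "degree_report")
}

#' @export
print.degree_report <- function(x, ...) {
  cat("<degree_report> ", nrow(x$degrees), " nodes, ", x$n_edges,
      " edges (", x$multi_edge_policy, " projection); mean degree ",
      format(x$mean_degree, digits = 4L), "\n", sep = "")
  invisible(x)
}

#' Find hub nodes
#'
#' A hub is a node whose degree strictly exceeds the network's mean degree;
#' ties at the mean are excluded.
#'
#' @param k A `kam`, `igraph` graph or `degree_report`.
#' @param ... Passed to [degree_report()] when `k` is not already a report.
#' @return A tibble `node`, `degree` sorted by decreasing degree, with the
#'   threshold (mean degree) as attribute `"threshold"`.
#' @export
find_hubs <- function(k, ...) {
  rep <- if (inherits(k, "degree_report")) k else degree_report(k, ...)
  if (nrow(rep$degrees) == 0L) abort("find_hubs needs at least one node")
  hubs <- rep$degrees[rep$degrees$degree > rep$mean_degree,
                      c("node", "degree")]
  hubs <- hubs[order(-hubs$degree, hubs$node), , drop = FALSE]
  attr(hubs, "threshold") <- rep$mean_degree
  hubs
}

#' Scale-free check by log-log degree-distribution regression
#'
#' Fits a least-squares line to log10(frequency) against log10(degree) over
#' degrees >= 1 (what the Cytoscape Network Analyzer reports), not a
#' maximum-likelihood power-law fit. The verdict is `"scale_free"` when the
#' exponent (slope) lies in \[-4, -1\] and R^2 is at least `r2_threshold`;
#' with fewer than `min_points` distinct positive degree values the verdict
#' is `"indeterminate"` rather than an error.
#'
#' @param k A `kam`, `igraph` graph or `degree_report`.
#' @param r2_threshold Minimum R^2 for a scale-free verdict (default 0.7).
#' @param min_points Minimum number of distinct degree values for a
#'   meaningful fit (default 10).
#' @param ... Passed to [degree_report()].
#' @return A one-row tibble: `exponent`, `r_squared`, `verdict`,
#'   `n_degree_values`.
#' @export
scale_free_check <- function(k, r2_threshold = 0.7, min_points = 10L, ...) {
  rep <- if (inherits(k, "degree_report")) k else degree_report(k, ...)
  h <- rep$histogram[rep$histogram$degree >= 1L, , drop = FALSE]
  if (nrow(h) < min_points) {
    return(tibble(exponent = NA_real_, r_squared = NA_real_,
                  verdict = "indeterminate", n_degree_values = nrow(h)))
  }
  fit <- stats::lm(log10(n) ~ log10(degree), data = h)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  verdict <- if (slope >= -4 && slope <= -1 && r2 >= r2_threshold) {
    "scale_free"
  } else "not_scale_free"
  tibble(exponent = slope, r_squared = r2, verdict = verdict,
         n_degree_values = nrow(h))
}

#' Compare two networks
#'
#' Node sharing is by canonical term key, edge sharing by
#' (source, target, relation), hub sharing via [find_hubs()] on each
#' network. Symmetric in its sharing counts.
#'
#' @param k1,k2 `kam` objects.
#' @return A one-row tibble with per-network node/edge/hub counts and the
#'   shared counts.
#' @export
compare_networks <- function(k1, k2) {
  stopifnot(inherits(k1, "kam"), inherits(k2, "kam"))
  ekey <- function(k) paste(k$edges$source, k$edges$target,
                            k$edges$relation, sep = "\r")
  hubs1 <- if (nrow(k1$nodes)) find_hubs(k1)$node else character()
  hubs2 <- if (nrow(k2$nodes)) find_hubs(k2)$node else character()
  tibble(
    nodes_a = nrow(k1$nodes), nodes_b = nrow(k2$nodes),
    edges_a = nrow(k1$edges), edges_b = nrow(k2$edges),
    shared_nodes = length(intersect(k1$nodes$key, k2$nodes$key)),
    shared_edges = length(intersect(ekey(k1), ekey(k2))),
    hubs_a = length(hubs1), hubs_b = length(hubs2),
    shared_hubs = length(intersect(hubs1, hubs2)))
}

normalize_sentence <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  gsub("\\s+", " ", str_trim(x))
}

document_sentences <- function(docs) {
  if (inherits(docs, "bel_document")) docs <- list(docs)
  unlist(lapply(docs, function(d) {
    vapply(d$blocks, function(b) b$evidence$text, character(1L))
  })) %||% character()
}

#' Evidence-sentence overlap between two document sets
#'
#' Sentences are normalized (lower-cased, punctuation stripped, whitespace
#' collapsed) and compared as sets. The headline figure is the Jaccard
#' fraction `|A intersect B| / |A union B|`; the per-set fractions are
#' reported alongside since either denominator convention occurs in
#' curation-comparison studies.
#'
#' @param docs_a,docs_b [bel_document()] objects or lists of them, or plain
#'   character vectors of sentences.
#' @return A one-row tibble: `jaccard_pct`, `pct_of_a`, `pct_of_b`, `n_a`,
#'   `n_b`, `n_shared`.
#' @export
evidence_overlap <- function(docs_a, docs_b) {
  sa <- if (is.character(docs_a)) docs_a else document_sentences(docs_a)
  sb <- if (is.character(docs_b)) docs_b else document_sentences(docs_b)
  sa <- unique(normalize_sentence(sa))
  sb <- unique(normalize_sentence(sb))
  inter <- length(intersect(sa, sb))
  uni <- length(union(sa, sb))
  tibble(
    jaccard_pct = if (uni) 100 * inter / uni else NA_real_,
    pct_of_a = if (length(sa)) 100 * inter / length(sa) else NA_real_,
    pct_of_b = if (length(sb)) 100 * inter / length(sb) else NA_real_,
    n_a = length(sa), n_b = length(sb), n_shared = inter)
}

round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Curation-efficiency metrics
#'
#' Derives minutes per statement and minutes per statement+annotation for
#' each curation arm, rounded half-up to one decimal (the convention of
#' curation-time tables).
#'
#' @param log A data frame with columns `arm`, `minutes`, `statements`,
#'   `annotations` (one row per arm, or per article — rows are summed
#'   within arm).
#' @return A tibble with one row per arm: the summed inputs plus
#'   `min_per_statement` and `min_per_statement_annotation`.
#' @export
#' @examples
#' curation_metrics(data.frame(
#'   arm = c("semi_automated", "manual"),
#'   minutes = c(395, 613), statements = c(234, 191),
#'   annotations = c(112, 46)))
curation_metrics <- function(log) {
  need <- c("arm", "minutes", "statements", "annotations")
  if (!all(need %in% names(log))) {
    abort(paste0("curation log needs columns: ", paste(need, collapse = ", ")))
  }
  out <- summarise(group_by(as_tibble(log), .data$arm),
                   minutes = sum(.data$minutes),
                   statements = sum(.data$statements),
                   annotations = sum(.data$annotations), .groups = "drop")
  if (any(out$statements <= 0)) {
    abort("curation metrics need statements > 0 in every arm")
  }
  out$min_per_statement <- round_half_up(out$minutes / out$statements, 1L)
  out$min_per_statement_annotation <- round_half_up(
    out$minutes / (out$statements + out$annotations), 1L)
  out
}
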