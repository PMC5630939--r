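# XGMML (Cytoscape's graph exchange XML). Node label = canonical term key,
# node attribute bel_function; edge attributes relation, causal,
# evidence_count. import(export(K)) preserves nodes, edges and these
# attributes (full evidence text lives in the KAM JSON, not in XGMML).

xgmml_ns <- "http://www.cs.rpi.edu/XGMML"

#' Export a KAM as XGMML
#'
#' @param k A `kam`.
#' @param path File path (`.xgmml`).
#' @param label Graph label.
#' @return The path, invisibly.
#' @export
export_xgmml <- function(k, path, label = "belminer network") {
  stopifnot(inherits(k, "kam"))
  x <- xml2::xml_new_root("graph", label = label, directed = "1",
                          xmlns = xgmml_ns)
  ids <- stats::setNames(seq_len(nrow(k$nodes)), k$nodes$key)
  for (i in seq_len(nrow(k$nodes))) {
    nd <- xml2::xml_add_child(x, "node", id = as.character(i),
                              label = k$nodes$key[i])
    xml2::xml_add_child(nd, "att", name = "bel_function", type = "string",
                        value = k$nodes$fn[i])
  }
  for (i in seq_len(nrow(k$edges))) {
    ed <- xml2::xml_add_child(
      x, "edge",
      source = as.character(ids[[k$edges$source[i]]]),
      target = as.character(ids[[k$edges$target[i]]]))
    xml2::xml_add_child(ed, "att", name = "relation", type = "string",
                        value = k$edges$relation[i])
    xml2::xml_add_child(ed, "att", name = "causal", type = "boolean",
                        value = tolower(as.character(k$edges$causal[i])))
    xml2::xml_add_child(ed, "att", name = "evidence_count", type = "integer",
                        value = as.character(k$edges$evidence_count[i]))
  }
  xml2::write_xml(x, path)
  invisible(path)
}

xg_att <- function(node, name) {
  att <- xml2::xml_find_first(
    node, sprintf("./x:att[@name='%s']", name),
    ns = c(x = xgmml_ns))
  if (inherits(att, "xml_missing")) {
    abort(sprintf("malformed XGMML: missing att '%s' under <%s>",
                  name, xml2::xml_name(node)),
          class = "bel_xgmml_error")
  }
  xml2::xml_attr(att, "value")
}

#' Import a KAM from XGMML
#'
#' @param path File path of an XGMML file written by [export_xgmml()] (or
#'   following the same attribute conventions).
#' @return A `kam`. Imported edges carry the `evidence_count` attribute;
#'   the evidence text itself is not part of XGMML and comes back empty.
#' @export
import_xgmml <- function(path) {
  x <- xml2::read_xml(path)
  nsm <- c(x = xgmml_ns)
  if (xml2::xml_name(xml2::xml_root(x)) != "graph") {
    abort("malformed XGMML: root element must be <graph>",
          class = "bel_xgmml_error")
  }
  node_els <- xml2::xml_find_all(x, "./x:node", ns = nsm)
  keys <- xml2::xml_attr(node_els, "label")
  ids <- xml2::xml_attr(node_els, "id")
  fns <- vapply(node_els, xg_att, character(1L), name = "bel_function")
  terms <- lapply(keys, parse_term)
  nodes <- bind_rows(lapply(terms, node_row))
  if (nrow(nodes) && !identical(nodes$fn, fns)) {
    abort("malformed XGMML: bel_function attribute disagrees with label",
          class = "bel_xgmml_error")
  }
  key_of <- stats::setNames(keys, ids)
  edge_els <- xml2::xml_find_all(x, "./x:edge", ns = nsm)
  if (length(edge_els)) {
    rel <- vapply(edge_els, xg_att, character(1L), name = "relation")
    edges <- tibble(
      source = unname(key_of[xml2::xml_attr(edge_els, "source")]),
      target = unname(key_of[xml2::xml_attr(edge_els, "target")]),
      relation = rel,
      causal = vapply(edge_els, xg_att, character(1L),
                      name = "causal") == "true",
      structural = FALSE,
      evidence = rep(list(tibble(doc = character(), pmid = character(),
                                 sentence = character())),
                     length(edge_els)),
      evidence_count = as.integer(
        vapply(edge_els, xg_att, character(1L), name = "evidence_count")))
    edges$structural <- !edges$causal & edges$evidence_count == 0L
  } else {
    edges <- empty_kam_edges()
  }
  nodes <- nodes[order(nodes$key), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$relation), ,
                 drop = FALSE]
  new_kam(nodes, edges)
}
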