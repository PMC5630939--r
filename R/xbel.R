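# XBEL: XML serialization of BEL documents. Schema (documented in the
# methods vignette):
#   <xbel version="1.0">
#     <header><name/><description/><version/></header>
#     <namespaces><namespace keyword="HGNC" url="-"/>...</namespaces>
#     <annotationDefinitions><annotationDefinition key=".." pattern=".."/></>
#     <statementGroup>
#       <evidence pmid=".." section=".." start=".." end="..">text</evidence>
#       <annotation key="Species">10090</annotation>
#       <statement fragment="complete">
#         <subject><term>p(HGNC:CYP4A11)</term></subject>
#         <relationship>increases</relationship>
#         <object><term>..</term> | <statement>..</statement></object>
#       </statement>
#     </statementGroup>
#   </xbel>
# Terms are carried as canonical BEL text; one statement-nesting level.

xbel_add_statement <- function(parent, s) {
  st <- xml2::xml_add_child(parent, "statement",
                            fragment = s$fragment_kind)
  if (!is.null(s$subject)) {
    subj <- xml2::xml_add_child(st, "subject")
    term <- xml2::xml_add_child(subj, "term")
    xml2::xml_set_text(term, serialize_term(s$subject))
  }
  rel <- xml2::xml_add_child(st, "relationship")
  xml2::xml_set_text(rel, s$relation)
  if (!is.null(s$object)) {
    obj <- xml2::xml_add_child(st, "object")
    if (inherits(s$object, "bel_statement")) {
      xbel_add_statement(obj, s$object)
    } else {
      term <- xml2::xml_add_child(obj, "term")
      xml2::xml_set_text(term, serialize_term(s$object))
    }
  }
  st
}

#' Write a BEL document as XBEL
#'
#' @param doc A validated [bel_document()].
#' @param path Optional file path; when `NULL` an `xml_document` is returned.
#' @return The `xml2::xml_document`, invisibly when written to a file.
#' @export
write_xbel <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "bel_document"))
  v <- validate_document(doc)
  if (nrow(v)) {
    abort(paste0("document does not validate; first violation: ",
                 v$message[1L]), class = "bel_validation_error")
  }
  x <- xml2::xml_new_root("xbel", version = "1.0")
  h <- xml2::xml_add_child(x, "header")
  for (f in c("name", "description", "version")) {
    node <- xml2::xml_add_child(h, f)
    xml2::xml_set_text(node, doc$header[[f]])
  }
  nss <- xml2::xml_add_child(x, "namespaces")
  for (ns in names(doc$namespaces)) {
    xml2::xml_add_child(nss, "namespace", keyword = ns,
                        url = doc$namespaces[[ns]])
  }
  ads <- xml2::xml_add_child(x, "annotationDefinitions")
  extra <- setdiff(names(doc$annotations), standard_annotation_keys)
  for (k in extra) {
    xml2::xml_add_child(ads, "annotationDefinition", key = k,
                        pattern = doc$annotations[[k]])
  }
  for (blk in doc$blocks) {
    sg <- xml2::xml_add_child(x, "statementGroup")
    ev <- blk$evidence
    evn <- xml2::xml_add_child(sg, "evidence")
    xml2::xml_set_text(evn, ev$text)
    if (!is.na(ev$pmid)) xml2::xml_set_attr(evn, "pmid", ev$pmid)
    if (!is.na(ev$section)) xml2::xml_set_attr(evn, "section", ev$section)
    if (!is.null(ev$span)) {
      xml2::xml_set_attr(evn, "start", ev$span[1L])
      xml2::xml_set_attr(evn, "end", ev$span[2L])
    }
    for (k in names(blk$annotations)) {
      an <- xml2::xml_add_child(sg, "annotation", key = k)
      xml2::xml_set_text(an, blk$annotations[[k]])
    }
    for (s in blk$statements) xbel_add_statement(sg, s)
  }
  if (is.null(path)) return(x)
  xml2::write_xml(x, path)
  invisible(x)
}

xbel_read_statement <- function(node) {
  subj_term <- xml2::xml_find_first(node, "./subject/term")
  rel <- xml2::xml_text(xml2::xml_find_first(node, "./relationship"))
  obj <- xml2::xml_find_first(node, "./object")
  subject <- if (!inherits(subj_term, "xml_missing")) {
    parse_term(xml2::xml_text(subj_term))
  }
  object <- NULL
  if (!inherits(obj, "xml_missing")) {
    inner_st <- xml2::xml_find_first(obj, "./statement")
    object <- if (!inherits(inner_st, "xml_missing")) {
      xbel_read_statement(inner_st)
    } else {
      parse_term(xml2::xml_text(xml2::xml_find_first(obj, "./term")))
    }
  }
  bel_statement(subject, rel, object)
}

#' Read a BEL document from XBEL
#'
#' @param x An `xml2::xml_document`, an XML string, or a path to an
#'   `.xbel`/`.xml` file.
#' @return A [bel_document()].
#' @export
read_xbel <- function(x) {
  if (!inherits(x, "xml_document")) x <- xml2::read_xml(x)
  root <- xml2::xml_root(x)
  if (xml2::xml_name(root) != "xbel") {
    abort("not an XBEL document (root element must be <xbel>)",
          class = "bel_xbel_error")
  }
  get1 <- function(xp) {
    n <- xml2::xml_find_first(root, xp)
    if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
  }
  ns_nodes <- xml2::xml_find_all(root, "./namespaces/namespace")
  namespaces <- stats::setNames(
    xml2::xml_attr(ns_nodes, "url"),
    toupper(xml2::xml_attr(ns_nodes, "keyword")))
  ad_nodes <- xml2::xml_find_all(root, "./annotationDefinitions/annotationDefinition")
  ann_defs <- stats::setNames(xml2::xml_attr(ad_nodes, "pattern"),
                              xml2::xml_attr(ad_nodes, "key"))
  blocks <- list()
  for (sg in xml2::xml_find_all(root, "./statementGroup")) {
    evn <- xml2::xml_find_first(sg, "./evidence")
    span <- NULL
    if (!is.na(xml2::xml_attr(evn, "start"))) {
      span <- c(as.integer(xml2::xml_attr(evn, "start")),
                as.integer(xml2::xml_attr(evn, "end")))
    }
    ev <- bel_evidence(xml2::xml_text(evn),
                       pmid = xml2::xml_attr(evn, "pmid"),
                       section = xml2::xml_attr(evn, "section"),
                       span = span)
    anns <- list()
    for (an in xml2::xml_find_all(sg, "./annotation")) {
      anns[[xml2::xml_attr(an, "key")]] <- xml2::xml_text(an)
    }
    stmts <- lapply(xml2::xml_find_all(sg, "./statement"),
                    xbel_read_statement)
    blocks[[length(blocks) + 1L]] <- bel_block(ev, anns, stmts)
  }
  doc <- bel_document(name = get1("./header/name"),
                      description = get1("./header/description"),
                      version = get1("./header/version"),
                      namespaces = namespaces, annotations = ann_defs,
                      blocks = blocks)
  v <- validate_document(doc)
  if (nrow(v)) {
    abort(paste0("XBEL content does not validate; first violation: ",
                 v$message[1L]), class = "bel_validation_error")
  }
  doc
}
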