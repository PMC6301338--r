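# Node-link JSON and GraphML export of knowledge networks.
#
# The JSON schema is stable and deterministic: nodes sorted by id, edges
# by their identity key, so byte-identical output is guaranteed for
# equal networks (used by query replay checks).

network_to_list <- function(network) {
  nodes <- arrange(network$nodes, .data$id)
  ord <- order(edge_signature(network$edges))
  e <- network$edges[ord, , drop = FALSE]
  list(
    schema = "belkit-node-link-v1",
    directed = TRUE,
    multigraph = TRUE,
    name = network$name,
    version = network$version,
    description = network$description,
    nodes = lapply(seq_len(nrow(nodes)), function(i) {
      list(id = nodes$id[i], func = nodes$func[i],
           namespace = nodes$namespace[i], name = nodes$name[i],
           variants = as.list(nodes$variants[[i]]))
    }),
    edges = lapply(seq_len(nrow(e)), function(i) {
      list(
        source = e$source[i], target = e$target[i],
        relation = e$relation[i], sign = e$sign[i],
        symmetric = e$symmetric[i],
        citation = list(
          db = e$citation_db[i], name = e$citation_name[i],
          ref = e$citation_ref[i], date = e$citation_date[i],
          authors = as.list(e$citation_authors[[i]])
        ),
        evidence = e$evidence[i],
        annotations = lapply(e$annotations[[i]], as.list),
        subject_activity = e$subject_activity[i],
        object_activity = e$object_activity[i]
      )
    })
  )
}

#' Serialize a network to node-link JSON
#'
#' @param network A `knowledge_network`.
#' @param path Optional output file; when NULL the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_network_json <- function(network, path = NULL) {
  json <- as.character(jsonlite::toJSON(network_to_list(network),
                                        auto_unbox = TRUE, digits = NA,
                                        null = "null"))
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(json)
}

#' Read a network from node-link JSON
#'
#' @param json JSON string, or path to a JSON file.
#' @return A `knowledge_network`.
#' @export
read_network_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nodes <- if (length(x$nodes)) {
    bind_rows(lapply(x$nodes, function(nd) {
      tibble(id = nd$id, func = nd$func, namespace = nd$namespace,
             name = nd$name, variants = list(as.character(unlist(nd$variants))))
    }))
  } else {
    empty_nodes()
  }
  edges <- if (length(x$edges)) {
    bind_rows(lapply(x$edges, function(ed) {
      tibble(
        source = ed$source, target = ed$target, relation = ed$relation,
        sign = as.integer(ed$sign), symmetric = isTRUE(ed$symmetric),
        citation_db = ed$citation$db %||% "",
        citation_name = ed$citation$name %||% "",
        citation_ref = ed$citation$ref %||% "",
        citation_date = ed$citation$date %||% "",
        citation_authors = list(as.character(unlist(ed$citation$authors))),
        evidence = ed$evidence %||% "",
        annotations = list(lapply(ed$annotations, function(v) as.character(unlist(v)))),
        subject_activity = isTRUE(ed$subject_activity),
        object_activity = isTRUE(ed$object_activity),
        line_number = NA_integer_
      )
    }))
  } else {
    empty_edges()
  }
  knowledge_network(nodes, edges, name = x$name %||% "",
                    version = x$version %||% "",
                    description = x$description %||% "")
}

#' Export a network to GraphML
#'
#' Writes a GraphML file with node attributes (function, namespace,
#' name) and edge attributes (relation, sign, citation, evidence) for
#' use in desktop network tools.
#'
#' @param network A `knowledge_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydefs <- list(
    list(id = "d_func", f = "node", name = "func"),
    list(id = "d_namespace", f = "node", name = "namespace"),
    list(id = "d_name", f = "node", name = "name"),
    list(id = "d_relation", f = "edge", name = "relation"),
    list(id = "d_sign", f = "edge", name = "sign"),
    list(id = "d_citation", f = "edge", name = "citation"),
    list(id = "d_evidence", f = "edge", name = "evidence")
  )
  for (k in keydefs) {
    xml2::xml_add_child(doc, "key", id = k$id, `for` = k$f,
                        attr.name = k$name, attr.type = "string")
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  nodes <- network$nodes
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = nodes$id[i])
    xml2::xml_add_child(nd, "data", nodes$func[i], key = "d_func")
    xml2::xml_add_child(nd, "data", nodes$namespace[i], key = "d_namespace")
    xml2::xml_add_child(nd, "data", nodes$name[i], key = "d_name")
  }
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(graph, "edge", source = e$source[i],
                              target = e$target[i])
    xml2::xml_add_child(ed, "data", e$relation[i], key = "d_relation")
    xml2::xml_add_child(ed, "data", as.character(e$sign[i]), key = "d_sign")
    xml2::xml_add_child(ed, "data",
                        paste0(e$citation_db[i], ":", e$citation_ref[i]),
                        key = "d_citation")
    xml2::xml_add_child(ed, "data", e$evidence[i], key = "d_evidence")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
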