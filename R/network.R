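# The KnowledgeNetwork model: a directed multigraph of typed nodes with
# qualified edges (relation, sign, citation, evidence, annotations).

RELATIONS <- c(
  "increases", "directlyIncreases", "decreases", "directlyDecreases",
  "association", "positiveCorrelation", "negativeCorrelation",
  "hasMember", "hasComponent", "isA", "orthologous",
  "transcribedTo", "translatedTo"
)

SHORT_RELATIONS <- c(
  "->" = "increases", "=>" = "directlyIncreases",
  "-|" = "decreases", "=|" = "directlyDecreases",
  "--" = "association"
)

SYMMETRIC_RELATIONS <- c("association", "positiveCorrelation", "negativeCorrelation")

relation_sign <- function(relation) {
  dplyr::case_when(
    relation %in% c("increases", "directlyIncreases") ~ 1L,
    relation %in% c("decreases", "directlyDecreases") ~ -1L,
    TRUE ~ 0L
  )
}

empty_nodes <- function() {
  tibble(
    id = character(), func = character(), namespace = character(),
    name = character(), variants = list()
  )
}

empty_edges <- function() {
  tibble(
    source = character(), target = character(), relation = character(),
    sign = integer(), symmetric = logical(),
    citation_db = character(), citation_ref = character(),
    citation_name = character(), citation_authors = list(),
    citation_date = character(),
    evidence = character(), annotations = list(),
    subject_activity = logical(), object_activity = logical(),
    line_number = integer()
  )
}

#' Construct a knowledge network
#'
#' A knowledge network is a directed multigraph: a `nodes` tibble keyed by
#' canonical node id and an `edges` tibble in which parallel edges (same
#' endpoints, different provenance) are allowed. Symmetric relations
#' (association and the correlations) are stored once with
#' `symmetric = TRUE` and traversed in both directions by all graph
#' operations.
#'
#' @param nodes Tibble with columns `id`, `func`, `namespace`, `name`,
#'   `variants` (list column). Missing columns of an empty input are
#'   tolerated.
#' @param edges Tibble with columns `source`, `target`, `relation`, and
#'   optionally the qualification columns (citation, evidence,
#'   annotations, activity flags); missing ones are filled with defaults,
#'   and `sign`/`symmetric` are always rederived from `relation`.
#' @param name,version,description Document metadata.
#' @return An object of class `knowledge_network`.
#' @export
#' @examples
#' nodes <- dplyr::bind_rows(
#'   node_spec_df("protein", "HGNC", c("RB1", "E2F4"))
#' )
#' edges <- tibble::tibble(source = nodes$id[1], target = nodes$id[2],
#'                         relation = "increases")
#' knowledge_network(nodes, edges)
knowledge_network <- function(nodes = empty_nodes(), edges = empty_edges(),
                              name = "", version = "", description = "") {
  nodes <- as_tibble(nodes)
  if (nrow(nodes) == 0) nodes <- empty_nodes()
  if (!"variants" %in% names(nodes)) nodes$variants <- rep(list(character()), nrow(nodes))
  edges <- as_tibble(edges)
  template <- empty_edges()
  if (nrow(edges) == 0) {
    edges <- template
  } else {
    n_e <- nrow(edges)
    defaults <- list(
      citation_db = "", citation_ref = "", citation_name = "",
      citation_authors = rep(list(character()), n_e), citation_date = "",
      evidence = "", annotations = rep(list(list()), n_e),
      subject_activity = FALSE, object_activity = FALSE,
      line_number = NA_integer_
    )
    for (col in setdiff(names(template), names(edges))) {
      edges[[col]] <- defaults[[col]]
    }
    for (col in c("citation_db", "citation_ref", "citation_name",
                  "citation_date", "evidence")) {
      edges[[col]][is.na(edges[[col]])] <- ""
    }
    edges$subject_activity[is.na(edges$subject_activity)] <- FALSE
    edges$object_activity[is.na(edges$object_activity)] <- FALSE
    edges$sign <- relation_sign(edges$relation)
    edges$symmetric <- edges$relation %in% SYMMETRIC_RELATIONS
    edges <- edges[names(template)]
  }
  missing_ep <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(missing_ep) > 0) {
    stop("edge endpoints not in node table: ",
         paste(missing_ep, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, version = version, description = description,
         nodes = nodes, edges = edges),
    class = "knowledge_network"
  )
}

#' Build node rows for several names at once
#'
#' Convenience for constructing node tables by hand (tests, examples).
#'
#' @param func Function class for all rows.
#' @param namespace Namespace keyword for all rows.
#' @param names Character vector of entity names.
#' @return A tibble of node rows with canonical ids.
#' @export
node_spec_df <- function(func, namespace, names) {
  bind_rows(lapply(names, function(nm) node_spec_row(node_spec(func, namespace, nm))))
}

#' @export
print.knowledge_network <- function(x, ...) {
  cat("<knowledge_network>",
      if (nzchar(x$name)) paste0(" ", x$name) else "",
      if (nzchar(x$version)) paste0(" v", x$version) else "", "\n", sep = "")
  cat("  nodes: ", nrow(x$nodes), "  edges: ", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

# Stable identity string of an edge (used for exact-duplicate
# deduplication and as the key accepted by delete_edge()).
edge_signature <- function(edges) {
  ann <- vapply(edges$annotations, function(a) {
    if (length(a) == 0) return("")
    keys <- sort(names(a))
    paste(vapply(keys, function(k) paste0(k, "=", paste(sort(a[[k]]), collapse = ",")), ""),
          collapse = ";")
  }, character(1))
  auth <- vapply(edges$citation_authors, function(a) paste(a, collapse = "|"), character(1))
  paste(edges$source, edges$target, edges$relation,
        edges$citation_db, edges$citation_ref, edges$citation_name, auth,
        edges$citation_date, edges$evidence, ann,
        edges$subject_activity, edges$object_activity,
        sep = "")
}

#' Edge keys of a network
#'
#' Returns the stable identity string of every edge, in edge-table order.
#' Two edges are exact duplicates (and are merged by [merge_networks()])
#' iff their keys are equal.
#'
#' @param network A `knowledge_network`.
#' @return Character vector of edge keys.
#' @export
edge_keys <- function(network) {
  edge_signature(network$edges)
}

dedup_edges <- function(edges) {
  edges[!duplicated(edge_signature(edges)), , drop = FALSE]
}

#' Compile a parsed BEL document into a knowledge network
#'
#' Each relational statement becomes one edge; nodes are deduplicated by
#' canonical identity. Statements that failed validation never reach the
#' document's statement table, so compilation is total.
#'
#' @param document A `bel_document` from [parse_bel_document()].
#' @return A `knowledge_network` with one edge per statement.
#' @export
compile_network <- function(document) {
  stopifnot(inherits(document, "bel_document"))
  st <- document$statements
  meta <- document$metadata
  if (nrow(st) == 0) {
    return(knowledge_network(name = meta$Name %||% "",
                             version = meta$Version %||% "",
                             description = meta$Description %||% ""))
  }
  subj_rows <- bind_rows(lapply(st$subject, node_spec_row))
  obj_rows <- bind_rows(lapply(st$object, node_spec_row))
  nodes <- distinct(bind_rows(subj_rows, obj_rows), .data$id, .keep_all = TRUE)
  edges <- tibble(
    source = subj_rows$id,
    target = obj_rows$id,
    relation = st$relation,
    sign = relation_sign(st$relation),
    symmetric = st$relation %in% SYMMETRIC_RELATIONS,
    citation_db = st$citation_db,
    citation_ref = st$citation_ref,
    citation_name = st$citation_name,
    citation_authors = st$citation_authors,
    citation_date = st$citation_date,
    evidence = st$evidence,
    annotations = st$annotations,
    subject_activity = st$subject_activity,
    object_activity = st$object_activity,
    line_number = st$line_number
  )
  knowledge_network(nodes, edges,
                    name = meta$Name %||% "",
                    version = meta$Version %||% "",
                    description = meta$Description %||% "")
}

#' Merge knowledge networks
#'
#' Node set is the union by identity; the edge multiset is the
#' concatenation with exact-duplicate edges (same endpoints, relation,
#' citation, evidence and annotations) deduplicated. Near-duplicates that
#' differ in provenance are kept, preserving multigraph semantics.
#'
#' @param networks Nonempty list of `knowledge_network` objects.
#' @return A single merged `knowledge_network`.
#' @export
merge_networks <- function(networks) {
  if (!is.list(networks) || length(networks) == 0 ||
      inherits(networks, "knowledge_network")) {
    stop("merge_networks() expects a nonempty list of knowledge networks",
         call. = FALSE)
  }
  stopifnot(all(vapply(networks, inherits, logical(1), "knowledge_network")))
  nodes <- distinct(bind_rows(lapply(networks, `[[`, "nodes")),
                    .data$id, .keep_all = TRUE)
  edges <- dedup_edges(bind_rows(lapply(networks, `[[`, "edges")))
  first <- networks[[1]]
  knowledge_network(nodes, edges, name = first$name,
                    version = first$version, description = first$description)
}

# Subnetwork over the given node ids. edges = "induced" keeps every edge
# with both endpoints retained; "causal" keeps only induced causal edges;
# "none" keeps no edges.
induce_subnetwork <- function(network, node_ids, edges = c("induced", "causal", "none")) {
  edges <- match.arg(edges)
  nodes <- network$nodes[network$nodes$id %in% node_ids, , drop = FALSE]
  e <- network$edges
  keep <- e$source %in% node_ids & e$target %in% node_ids
  if (edges == "causal") keep <- keep & e$sign != 0L
  if (edges == "none") keep <- rep(FALSE, nrow(e))
  knowledge_network(nodes, e[keep, , drop = FALSE], name = network$name,
                    version = network$version, description = network$description)
}

# Subnetwork built from an edge subset plus its endpoints.
edges_subnetwork <- function(network, keep) {
  e <- network$edges[keep, , drop = FALSE]
  ids <- unique(c(e$source, e$target))
  nodes <- network$nodes[network$nodes$id %in% ids, , drop = FALSE]
  knowledge_network(nodes, e, name = network$name,
                    version = network$version, description = network$description)
}

# igraph view of a network. Symmetric edges contribute one arc in each
# direction so every traversal treats them bidirectionally; causal_only
# restricts to edges with sign != 0.
as_belkit_igraph <- function(network, causal_only = FALSE, simple = FALSE) {
  e <- network$edges
  if (causal_only) e <- e[e$sign != 0L, , drop = FALSE]
  from <- c(e$source, e$target[e$symmetric])
  to <- c(e$target, e$source[e$symmetric])
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = network$nodes$id, stringsAsFactors = FALSE)
  )
  if (simple) g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  g
}

#' @rdname glance.knowledge_network
#' @exportS3Method generics::tidy
tidy.knowledge_network <- function(x, ...) {
  select(x$edges, "source", "target", "relation", "sign", "symmetric",
         "citation_db", "citation_ref", "evidence")
}

#' Summarize a knowledge network in broom style
#'
#' `glance()` returns a one-row tibble of headline measures (node, edge
#' and citation counts, density, average degree); `tidy()` returns the
#' edge table with one row per relational statement.
#'
#' @param x A `knowledge_network`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::glance
glance.knowledge_network <- function(x, ...) {
  s <- network_statistics(x)
  tibble(
    nodes = s$node_count, edges = s$edge_count,
    citations = s$citation_count,
    density = s$density, average_degree = s$average_degree
  )
}
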