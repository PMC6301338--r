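# Named network transformations applied in query pipelines and
# interactive exploration. All transformations are pure: they return a
# new network and never modify their input.

#' Keep only causal edges
#'
#' Retains edges with nonzero sign (increases/directlyIncreases,
#' decreases/directlyDecreases) and drops nodes left isolated.
#'
#' @param network A `knowledge_network`.
#' @return A `knowledge_network`.
#' @export
extract_causal <- function(network) {
  e <- network$edges[network$edges$sign != 0L, , drop = FALSE]
  ids <- unique(c(e$source, e$target))
  knowledge_network(network$nodes[network$nodes$id %in% ids, , drop = FALSE], e,
                    name = network$name, version = network$version,
                    description = network$description)
}

#' Remove pathology nodes
#'
#' Pathology nodes are often uninformative hubs in disease-specific
#' networks; this deletes them together with their incident edges.
#' Other nodes are kept even if left isolated.
#'
#' @param network A `knowledge_network`.
#' @return A `knowledge_network`.
#' @export
remove_pathologies <- function(network) {
  keep <- network$nodes$id[network$nodes$func != "pathology"]
  drop_to_nodes(network, keep)
}

#' Delete nodes by namespace
#'
#' Deletes nodes whose namespace keyword is in `namespaces` (e.g. MGI
#' and RGD to drop mouse and rat genes), with their incident edges.
#'
#' @param network A `knowledge_network`.
#' @param namespaces Character vector of namespace keywords.
#' @return A `knowledge_network`.
#' @export
delete_namespace_nodes <- function(network, namespaces) {
  keep <- network$nodes$id[!network$nodes$namespace %in% namespaces]
  drop_to_nodes(network, keep)
}

# keep exactly these nodes and the edges among them
drop_to_nodes <- function(network, keep) {
  e <- network$edges
  e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  knowledge_network(network$nodes[network$nodes$id %in% keep, , drop = FALSE], e,
                    name = network$name, version = network$version,
                    description = network$description)
}

# an unqualified structural edge (central dogma, membership enrichment)
synthetic_edge <- function(source, target, relation) {
  tibble(
    source = source, target = target, relation = relation,
    sign = relation_sign(relation),
    symmetric = relation %in% SYMMETRIC_RELATIONS,
    citation_db = "", citation_ref = "", citation_name = "",
    citation_authors = list(character(0)), citation_date = "",
    evidence = "", annotations = list(list()),
    subject_activity = FALSE, object_activity = FALSE,
    line_number = NA_integer_
  )
}

#' Enrich protein and RNA origins
#'
#' For each protein node adds the corresponding RNA node and a
#' `translatedTo` edge (RNA to protein); then for each RNA or miRNA node
#' adds the corresponding gene node and a `transcribedTo` edge (gene to
#' RNA). Existing nodes and edges are reused, so the transformation is
#' idempotent.
#'
#' @param network A `knowledge_network`.
#' @return A `knowledge_network`.
#' @export
enrich_protein_rna_origins <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  new_nodes <- list()
  new_edges <- list()
  have_node <- function(id) id %in% nodes$id ||
    id %in% vapply(new_nodes, function(x) x$id, character(1))
  have_edge <- function(s, t, rel) {
    any(edges$source == s & edges$target == t & edges$relation == rel) ||
      any(vapply(new_edges, function(x) x$source == s && x$target == t && x$relation == rel, logical(1)))
  }
  add_origin <- function(rows, origin_func, relation) {
    for (i in seq_len(nrow(rows))) {
      child <- rows[i, ]
      parent <- node_spec(origin_func, child$namespace, child$name)
      pid <- node_id(parent)
      if (!have_node(pid)) new_nodes[[length(new_nodes) + 1L]] <<- node_spec_row(parent)
      if (!have_edge(pid, child$id, relation)) {
        new_edges[[length(new_edges) + 1L]] <<- synthetic_edge(pid, child$id, relation)
      }
    }
  }
  add_origin(nodes[nodes$func == "protein", , drop = FALSE], "rna", "translatedTo")
  # include RNAs just created as translation origins
  nodes2 <- bind_rows(c(list(nodes), new_nodes))
  add_origin(nodes2[nodes2$func %in% c("rna", "mirna"), , drop = FALSE],
             "gene", "transcribedTo")
  knowledge_network(
    distinct(bind_rows(c(list(nodes), new_nodes)), .data$id, .keep_all = TRUE),
    bind_rows(c(list(edges), new_edges)),
    name = network$name, version = network$version,
    description = network$description
  )
}

# quotient of the network under a node id mapping; self-loops arising
# from collapsed groups are dropped for the listed relations
collapse_nodes <- function(network, mapping, new_node_rows,
                           drop_selfloop_relations = character()) {
  e <- network$edges
  e$source <- unname(mapping[e$source])
  e$target <- unname(mapping[e$target])
  selfloop <- e$source == e$target & e$relation %in% drop_selfloop_relations
  e <- dedup_edges(e[!selfloop, , drop = FALSE])
  knowledge_network(new_node_rows, e, name = network$name,
                    version = network$version, description = network$description)
}

#' Collapse variant nodes
#'
#' Merges every node carrying variants (e.g. `p(HGNC:X, pmod(Ph))`) into
#' the variant-free node of the same function, namespace and name;
#' edges are re-targeted and exact duplicates deduplicated.
#'
#' @param network A `knowledge_network`.
#' @return A `knowledge_network`.
#' @export
collapse_variants <- function(network) {
  nodes <- network$nodes
  base_id <- vapply(seq_len(nrow(nodes)), function(i) {
    node_id(node_spec(nodes$func[i], nodes$namespace[i], nodes$name[i]))
  }, character(1))
  mapping <- setNames(base_id, nodes$id)
  new_nodes <- nodes
  new_nodes$id <- base_id
  new_nodes$variants <- rep(list(character()), nrow(new_nodes))
  new_nodes <- distinct(new_nodes, .data$id, .keep_all = TRUE)
  collapse_nodes(network, mapping, new_nodes)
}

#' Collapse gene, RNA and protein nodes to genes
#'
#' Maps protein, RNA and miRNA nodes to the gene node of the same
#' namespace and name (variants dropped); `transcribedTo`/`translatedTo`
#' edges within a collapsed group are removed and remaining edges
#' re-targeted and deduplicated. Idempotent.
#'
#' @param network A `knowledge_network`.
#' @return A `knowledge_network`.
#' @export
collapse_to_genes <- function(network) {
  nodes <- network$nodes
  central <- nodes$func %in% c("protein", "rna", "mirna", "gene")
  new_func <- ifelse(central, "gene", nodes$func)
  mapped_id <- vapply(seq_len(nrow(nodes)), function(i) {
    if (central[i]) {
      node_id(node_spec("gene", nodes$namespace[i], nodes$name[i]))
    } else {
      nodes$id[i]
    }
  }, character(1))
  mapping <- setNames(mapped_id, nodes$id)
  new_nodes <- nodes
  new_nodes$id <- mapped_id
  new_nodes$func <- new_func
  new_nodes$variants[central] <- rep(list(character()), sum(central))
  new_nodes <- distinct(new_nodes, .data$id, .keep_all = TRUE)
  collapse_nodes(network, mapping, new_nodes,
                 drop_selfloop_relations = c("transcribedTo", "translatedTo"))
}

#' Enrich a network with family and complex members
#'
#' For every node of the network that appears as the subject of
#' `hasMember`/`hasComponent` edges in the resource network, adds those
#' member/component nodes and edges (direct membership only, one hop).
#'
#' @param network A `knowledge_network`.
#' @param resource A `knowledge_network` of membership edges (e.g. from
#'   [generate_family_resource()]).
#' @return A `knowledge_network`.
#' @export
enrich_members <- function(network, resource) {
  stopifnot(inherits(resource, "knowledge_network"))
  re <- resource$edges
  keep <- re$relation %in% c("hasMember", "hasComponent") &
    re$source %in% network$nodes$id
  re <- re[keep, , drop = FALSE]
  if (nrow(re) == 0) return(network)
  member_nodes <- resource$nodes[resource$nodes$id %in% unique(c(re$source, re$target)), , drop = FALSE]
  knowledge_network(
    distinct(bind_rows(network$nodes, member_nodes), .data$id, .keep_all = TRUE),
    dedup_edges(bind_rows(network$edges, re)),
    name = network$name, version = network$version,
    description = network$description
  )
}

#' Delete a single node
#'
#' Removes the node and its incident edges; errors if the node is not in
#' the network.
#'
#' @param network A `knowledge_network`.
#' @param node Canonical node id.
#' @return A `knowledge_network`.
#' @export
delete_node <- function(network, node) {
  if (!node %in% network$nodes$id) {
    stop("node not in network: ", node, call. = FALSE)
  }
  drop_to_nodes(network, setdiff(network$nodes$id, node))
}

#' Delete a single edge
#'
#' Removes the edge with the given key (see [edge_keys()]); errors if
#' absent.
#'
#' @param network A `knowledge_network`.
#' @param edge_key Edge identity string.
#' @return A `knowledge_network`.
#' @export
delete_edge <- function(network, edge_key) {
  keys <- edge_keys(network)
  hit <- which(keys == edge_key)
  if (length(hit) == 0) stop("edge not in network", call. = FALSE)
  net <- network
  net$edges <- network$edges[-hit[1], , drop = FALSE]
  net
}

#' Random subsample of a large network
#'
#' Networks at or below `max_nodes` are returned unchanged; larger ones
#' are reduced to the induced subgraph on a uniformly sampled node subset
#' of size `max_nodes`, deterministic given `seed`.
#'
#' @param network A `knowledge_network`.
#' @param max_nodes Maximum number of nodes to keep.
#' @param seed Integer seed fixing the sample.
#' @return A `knowledge_network`.
#' @export
random_subsample <- function(network, max_nodes, seed = 0L) {
  if (nrow(network$nodes) <= max_nodes) return(network)
  ids <- sort(network$nodes$id)
  keep <- withr::with_seed(seed, sample(ids, max_nodes))
  induce_subnetwork(network, keep)
}

#' Highlight nodes and edges by predicate
#'
#' Pure selection: returns the matching node and edge rows without
#' modifying the network.
#'
#' @param network A `knowledge_network`.
#' @param node_predicate Function over a node row tibble returning a
#'   logical vector (or NULL to select none).
#' @param edge_predicate Function over the edge tibble returning a
#'   logical vector (or NULL to select none).
#' @return List with tibbles `nodes` and `edges`.
#' @export
highlight_selection <- function(network, node_predicate = NULL, edge_predicate = NULL) {
  nodes <- if (is.null(node_predicate)) network$nodes[0, ] else
    network$nodes[node_predicate(network$nodes), , drop = FALSE]
  edges <- if (is.null(edge_predicate)) network$edges[0, ] else
    network$edges[edge_predicate(network$edges), , drop = FALSE]
  list(nodes = nodes, edges = edges)
}

#' The transformation registry
#'
#' Named registry of the transformations addressable from query
#' pipelines, each entry holding the function (called as
#' `fn(network, args, catalog)`), a human-readable argument schema, and
#' whether the transformation may add nodes. New transformations can be
#' registered with [register_transformation()].
#'
#' @return Named list of registry entries.
#' @export
transformation_registry <- function() {
  entry <- function(fn, schema = "", adds_nodes = FALSE) {
    list(fn = fn, schema = schema, adds_nodes = adds_nodes)
  }
  list(
    extract_causal = entry(function(net, args, catalog) extract_causal(net)),
    remove_pathologies = entry(function(net, args, catalog) remove_pathologies(net)),
    delete_namespace_nodes = entry(
      function(net, args, catalog) delete_namespace_nodes(net, unlist(args$namespaces)),
      schema = "namespaces: [keyword]"
    ),
    enrich_protein_rna_origins = entry(
      function(net, args, catalog) enrich_protein_rna_origins(net),
      adds_nodes = TRUE
    ),
    collapse_variants = entry(function(net, args, catalog) collapse_variants(net)),
    collapse_to_genes = entry(function(net, args, catalog) collapse_to_genes(net)),
    enrich_members = entry(
      function(net, args, catalog) {
        resource <- if (inherits(args$resource, "knowledge_network")) {
          args$resource
        } else {
          catalog[[args$resource]] %||%
            stop("enrich_members: resource network not in catalog: ",
                 args$resource, call. = FALSE)
        }
        enrich_members(net, resource)
      },
      schema = "resource: network id", adds_nodes = TRUE
    ),
    delete_node = entry(
      function(net, args, catalog) delete_node(net, args$node),
      schema = "node: id"
    ),
    delete_edge = entry(
      function(net, args, catalog) delete_edge(net, args$edge_key),
      schema = "edge_key: key"
    ),
    random_subsample = entry(
      function(net, args, catalog) random_subsample(net, as.integer(args$max_nodes),
                                                    seed = as.integer(args$seed %||% 0L)),
      schema = "max_nodes: int, seed: int"
    )
  )
}

#' Register a transformation
#'
#' @param registry Registry from [transformation_registry()].
#' @param name Unique transformation name.
#' @param fn Function `(network, args, catalog) -> knowledge_network`.
#' @param schema Human-readable argument schema.
#' @param adds_nodes Whether the transformation may add nodes.
#' @return The extended registry.
#' @export
register_transformation <- function(registry, name, fn, schema = "", adds_nodes = FALSE) {
  if (name %in% names(registry)) {
    stop("transformation already registered: ", name, call. = FALSE)
  }
  registry[[name]] <- list(fn = fn, schema = schema, adds_nodes = adds_nodes)
  registry
}
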