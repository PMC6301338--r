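# The three-step query model: network selection, seeding, and a
# transformation pipeline, stored as a replayable transaction.
#
# Seed methods extract a relevant subnetwork from the assembled network.
# Neighborhood distance ignores edge direction; shortest/all path
# seeding respects direction, with symmetric edges traversable both
# ways; upstream/downstream follow causal edges only.

check_seed_nodes <- function(network, nodes) {
  if (length(nodes) == 0) stop("seed node list is empty", call. = FALSE)
  missing <- setdiff(nodes, network$nodes$id)
  if (length(missing) > 0) {
    stop("seed node(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Seed a subnetwork by Nth neighbors
#'
#' Induces the subgraph over all nodes at undirected path length at most
#' `n` from any query node (symmetric edges traversed; causal edge
#' direction ignored for distance), with all edges among them.
#'
#' @param network A `knowledge_network`.
#' @param nodes Character vector of seed node ids (see [node_id()]).
#' @param n Maximum path length, at least 1.
#' @return A `knowledge_network` subgraph.
#' @export
seed_neighbors <- function(network, nodes, n = 1L) {
  check_seed_nodes(network, nodes)
  stopifnot(n >= 1)
  g <- as_belkit_igraph(network)
  reach <- igraph::ego(g, order = n, nodes = nodes, mode = "all")
  keep <- unique(c(nodes, unlist(lapply(reach, function(v) v$name))))
  induce_subnetwork(network, keep)
}

# two-layer expansion along causal edges; mode "in" for upstream,
# "out" for downstream
seed_causal_layers <- function(network, nodes, mode) {
  check_seed_nodes(network, nodes)
  e <- network$edges[network$edges$sign != 0L, , drop = FALSE]
  expand <- function(layer) {
    extra <- if (mode == "in") e$source[e$target %in% layer]
             else e$target[e$source %in% layer]
    unique(c(layer, extra))
  }
  keep <- expand(expand(unique(nodes)))
  induce_subnetwork(network, keep, edges = "causal")
}

#' Seed an upstream subnetwork
#'
#' Collects nodes with causal edges targeting the query nodes, repeats a
#' second time for that subnetwork to include a second layer, and then
#' induces all causal edges between the resulting nodes.
#'
#' @inheritParams seed_neighbors
#' @return A `knowledge_network` of causal edges.
#' @export
seed_upstream <- function(network, nodes) {
  seed_causal_layers(network, nodes, "in")
}

#' Seed a downstream subnetwork
#'
#' Mirror of [seed_upstream()] on outgoing causal edges.
#'
#' @inheritParams seed_neighbors
#' @return A `knowledge_network` of causal edges.
#' @export
seed_downstream <- function(network, nodes) {
  seed_causal_layers(network, nodes, "out")
}

#' Seed by shortest paths between query nodes
#'
#' For every ordered pair of query nodes, collects all nodes lying on any
#' shortest directed path (symmetric edges usable in both directions) and
#' induces all edges among the union. Pairs with no path contribute
#' nothing.
#'
#' @inheritParams seed_neighbors
#' @return A `knowledge_network` subgraph.
#' @export
seed_shortest_paths <- function(network, nodes) {
  check_seed_nodes(network, nodes)
  nodes <- unique(nodes)
  if (length(nodes) < 2) stop("shortest-path seeding needs at least 2 query nodes", call. = FALSE)
  g <- as_belkit_igraph(network)
  keep <- character(0)
  for (s in nodes) {
    targets <- setdiff(nodes, s)
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = targets, mode = "out")
    )
    for (p in sp$vpaths) keep <- c(keep, p$name)
  }
  keep <- unique(c(nodes, keep))
  induce_subnetwork(network, keep)
}

#' Seed by all bounded-length paths between query nodes
#'
#' Collects nodes on all simple directed paths of at most `max_length`
#' edges between ordered pairs of query nodes (default 6, i.e. length
#' less than seven) and induces all edges among them.
#'
#' @inheritParams seed_neighbors
#' @param max_length Maximum number of edges per path.
#' @return A `knowledge_network` subgraph.
#' @export
seed_all_paths <- function(network, nodes, max_length = 6L) {
  check_seed_nodes(network, nodes)
  nodes <- unique(nodes)
  if (length(nodes) < 2) stop("all-paths seeding needs at least 2 query nodes", call. = FALSE)
  g <- as_belkit_igraph(network)
  keep <- character(0)
  for (s in nodes) {
    for (t in setdiff(nodes, s)) {
      paths <- igraph::all_simple_paths(g, from = s, to = t,
                                        mode = "out", cutoff = max_length)
      for (p in paths) keep <- c(keep, p$name)
    }
  }
  keep <- unique(c(nodes, keep))
  induce_subnetwork(network, keep)
}

#' Seed by citation provenance
#'
#' Builds a subnetwork from all edges with provenance from articles with
#' the given PubMed identifiers, plus their endpoints.
#'
#' @param network A `knowledge_network`.
#' @param pmids Character vector of PubMed identifiers.
#' @return A `knowledge_network`.
#' @export
seed_provenance <- function(network, pmids) {
  if (length(pmids) == 0) stop("no PubMed identifiers given", call. = FALSE)
  e <- network$edges
  keep <- tolower(e$citation_db) == "pubmed" & e$citation_ref %in% as.character(pmids)
  edges_subnetwork(network, keep)
}

#' Seed by citation authors
#'
#' Builds a subnetwork from all edges asserted in articles written by
#' authors with the given names (exact, case-insensitive full-string
#' match), plus their endpoints.
#'
#' @param network A `knowledge_network`.
#' @param names Character vector of author names.
#' @return A `knowledge_network`.
#' @export
seed_authors <- function(network, names) {
  if (length(names) == 0) stop("no author names given", call. = FALSE)
  wanted <- tolower(names)
  keep <- vapply(network$edges$citation_authors, function(a) {
    any(tolower(a) %in% wanted)
  }, logical(1))
  edges_subnetwork(network, keep)
}

#' Seed by edge annotations
#'
#' Builds a subnetwork from all edges matching the given biological or
#' contextual annotations: within a key, any listed value matches (OR);
#' across keys, every filter key must match (AND). Plus endpoints.
#'
#' @param network A `knowledge_network`.
#' @param filters Named list mapping annotation keyword to a character
#'   vector of acceptable values.
#' @return A `knowledge_network`.
#' @export
seed_annotations <- function(network, filters) {
  if (length(filters) == 0 || is.null(names(filters))) {
    stop("annotation filter must be a nonempty named list", call. = FALSE)
  }
  keep <- vapply(network$edges$annotations, function(ann) {
    all(vapply(names(filters), function(k) {
      length(intersect(ann[[k]] %||% character(0), filters[[k]])) > 0
    }, logical(1)))
  }, logical(1))
  edges_subnetwork(network, keep)
}

# node/edge-wise union of subnetworks (all subgraphs of one assembly)
union_networks <- function(networks) {
  nodes <- distinct(bind_rows(lapply(networks, `[[`, "nodes")),
                    .data$id, .keep_all = TRUE)
  edges <- dedup_edges(bind_rows(lapply(networks, `[[`, "edges")))
  first <- networks[[1]]
  knowledge_network(nodes, edges, name = first$name,
                    version = first$version, description = first$description)
}

SEED_METHODS <- c("neighbors", "upstream", "downstream", "shortest_paths",
                  "all_paths", "provenance", "authors", "annotations")

apply_seed <- function(network, seed) {
  method <- seed$method
  payload <- seed$payload
  switch(method,
    neighbors = seed_neighbors(network, unlist(payload$nodes),
                               n = as.integer(payload$n %||% 1L)),
    upstream = seed_upstream(network, unlist(payload$nodes)),
    downstream = seed_downstream(network, unlist(payload$nodes)),
    shortest_paths = seed_shortest_paths(network, unlist(payload$nodes)),
    all_paths = seed_all_paths(network, unlist(payload$nodes),
                               max_length = as.integer(payload$max_length %||% 6L)),
    provenance = seed_provenance(network, unlist(payload$pmids)),
    authors = seed_authors(network, unlist(payload$names)),
    annotations = seed_annotations(network, lapply(payload$filters, unlist)),
    stop("unknown seed method: ", method, call. = FALSE)
  )
}

#' Construct a query transaction
#'
#' A query stores a network selection, a list of seed specifications
#' (combined by union) and an ordered transformation pipeline. Queries
#' are replayable ([run_query()]), serializable to JSON
#' ([query_to_json()]), hashable ([query_id()]) and reversible step by
#' step ([undo_query()]).
#'
#' @param network_ids Ordered character vector of network identifiers to
#'   assemble (merged before seeding).
#' @param seeds List of seed specifications, each
#'   `list(method = , payload = )` with `method` one of
#'   `r paste(SEED_METHODS, collapse = ", ")`.
#' @param pipeline List of transformation steps, each
#'   `list(name = , args = )` with `name` registered in the
#'   transformation registry.
#' @return An object of class `bel_query`.
#' @export
bel_query <- function(network_ids, seeds = list(), pipeline = list()) {
  stopifnot(is.character(network_ids), length(network_ids) >= 1)
  for (s in seeds) {
    if (!is.list(s) || is.null(s$method) || !s$method %in% SEED_METHODS) {
      stop("invalid seed specification", call. = FALSE)
    }
    if (length(s$payload) == 0) stop("seed payload is empty", call. = FALSE)
  }
  for (p in pipeline) {
    if (!is.list(p) || is.null(p$name)) {
      stop("invalid pipeline entry", call. = FALSE)
    }
  }
  structure(
    list(network_ids = network_ids, seeds = seeds, pipeline = pipeline),
    class = "bel_query"
  )
}

#' @export
print.bel_query <- function(x, ...) {
  cat("<bel_query> networks:", paste(x$network_ids, collapse = ", "), "\n")
  cat("  seeds:", length(x$seeds),
      " pipeline:", paste(vapply(x$pipeline, `[[`, "", "name"), collapse = " -> "), "\n")
  invisible(x)
}

#' Run a query transaction
#'
#' Assembles the selected networks by [merge_networks()], applies each
#' seed specification to the assembly and unions the results (an empty
#' seed list selects the whole assembly), then applies the
#' transformation pipeline left to right. Inputs are never modified;
#' rerunning on an identical catalog yields an identical result.
#'
#' @param query A `bel_query`.
#' @param catalog Named list mapping network id to `knowledge_network`.
#' @param registry Transformation registry from [transformation_registry()].
#' @return The resulting `knowledge_network`.
#' @export
run_query <- function(query, catalog, registry = transformation_registry()) {
  stopifnot(inherits(query, "bel_query"))
  missing_ids <- setdiff(query$network_ids, names(catalog))
  if (length(missing_ids) > 0) {
    stop("unknown network id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  step_names <- vapply(query$pipeline, `[[`, "", "name")
  unknown <- setdiff(step_names, names(registry))
  if (length(unknown) > 0) {
    stop("unknown transformation(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  assembly <- merge_networks(catalog[query$network_ids])
  net <- if (length(query$seeds) == 0) {
    assembly
  } else {
    union_networks(lapply(query$seeds, function(s) apply_seed(assembly, s)))
  }
  for (step in query$pipeline) {
    entry <- registry[[step$name]]
    net <- entry$fn(net, step$args %||% list(), catalog)
  }
  net
}

#' Undo the last query step
#'
#' Removes the last pipeline entry; if the pipeline is empty, removes the
#' last seed; if both are empty the query cannot be unwound further.
#'
#' @param query A `bel_query`.
#' @return The shortened `bel_query`.
#' @export
undo_query <- function(query) {
  stopifnot(inherits(query, "bel_query"))
  if (length(query$pipeline) > 0) {
    query$pipeline <- query$pipeline[-length(query$pipeline)]
  } else if (length(query$seeds) > 0) {
    query$seeds <- query$seeds[-length(query$seeds)]
  } else {
    stop("nothing to undo", call. = FALSE)
  }
  query
}

# canonical JSON: recursively name-sorted, unboxed scalars
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x) > 0) {
      x <- x[order(names(x))]
    }
    lapply(x, canonicalize)
  } else {
    x
  }
}

#' Serialize a query to JSON
#'
#' @param query A `bel_query`.
#' @param canonical Sort map keys (used for hashing).
#' @return JSON string.
#' @export
query_to_json <- function(query, canonical = TRUE) {
  x <- unclass(query)
  if (canonical) x <- canonicalize(x)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

#' Deserialize a query from JSON
#'
#' @param json JSON string or path to a JSON file.
#' @return A `bel_query`.
#' @export
query_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  bel_query(
    network_ids = as.character(unlist(x$network_ids)),
    seeds = x$seeds %||% list(),
    pipeline = x$pipeline %||% list()
  )
}

#' Unique identifier of a query
#'
#' SHA-256 content hash of the canonical JSON serialization (map keys
#' sorted), so equal queries always hash to the same identifier,
#' independent of the serialization order of annotation maps.
#'
#' @param query A `bel_query`.
#' @return Hex identifier string.
#' @export
query_id <- function(query) {
  digest::digest(query_to_json(query, canonical = TRUE),
                 algo = "sha256", serialize = FALSE)
}
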