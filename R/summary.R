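# Statistical summary and biogrammar motif summary of a knowledge
# network.
#
# The biogrammar summary searches for small pre-defined motifs that are
# informative about the robustness and consistency of curation: the
# contradictory pair (the same ordered node pair asserted with both
# increasing and decreasing causal statements) and the inconsistent
# negative-correlation triple (three nodes pairwise negatively
# correlated, which is sign-inconsistent as a cycle).

#' Statistical summary of a knowledge network
#'
#' Counts nodes, edges and distinct citations; tallies node functions,
#' relation types, namespaces and annotation keywords; and computes
#' network-theoretic measures. Density treats the multigraph as a simple
#' directed graph of connected ordered pairs (symmetric edges count both
#' orders) over `n * (n - 1)` possible pairs; average degree is
#' `2 * |edges| / n` on the multigraph.
#'
#' @param network A `knowledge_network`.
#' @param top_n How many nodes to report in `top_centrality` (by
#'   betweenness on the directed simple graph).
#' @return A list of class `network_summary` with fields `node_count`,
#'   `edge_count`, `citation_count`, `function_counts`,
#'   `relation_counts`, `namespace_counts`, `annotation_counts`,
#'   `density`, `average_degree`, `top_centrality`.
#' @export
network_statistics <- function(network, top_n = 10L) {
  stopifnot(inherits(network, "knowledge_network"))
  nodes <- network$nodes
  edges <- network$edges
  n <- nrow(nodes)

  cit <- edges[nzchar(edges$citation_db) | nzchar(edges$citation_ref), , drop = FALSE]
  citation_count <- length(unique(paste(cit$citation_db, cit$citation_ref, sep = "|")))

  tally <- function(x) {
    if (length(x) == 0) return(integer(0))
    t <- table(x)
    setNames(as.integer(t), names(t))
  }
  ann_keys <- unlist(lapply(edges$annotations, names))

  # density over distinct connected ordered pairs
  if (n >= 2 && nrow(edges) > 0) {
    nonloop <- edges[edges$source != edges$target, , drop = FALSE]
    pairs <- unique(c(
      paste(nonloop$source, nonloop$target, sep = "\r"),
      paste(nonloop$target[nonloop$symmetric], nonloop$source[nonloop$symmetric], sep = "\r")
    ))
    density <- length(pairs) / (n * (n - 1))
  } else {
    density <- 0
  }
  average_degree <- if (n >= 1) 2 * nrow(edges) / n else 0

  top_centrality <- numeric(0)
  if (n > 0) {
    g <- as_belkit_igraph(network, simple = TRUE)
    btw <- igraph::betweenness(g, directed = TRUE)
    btw <- sort(btw, decreasing = TRUE)
    top_centrality <- head(btw, top_n)
  }

  structure(
    list(
      node_count = n,
      edge_count = nrow(edges),
      citation_count = citation_count,
      function_counts = tally(nodes$func),
      relation_counts = tally(edges$relation),
      namespace_counts = tally(nodes$namespace),
      annotation_counts = tally(ann_keys),
      density = density,
      average_degree = average_degree,
      top_centrality = top_centrality
    ),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary>\n")
  cat("  nodes:", x$node_count, " edges:", x$edge_count,
      " citations:", x$citation_count, "\n")
  cat("  density:", format(x$density, digits = 4),
      " average degree:", format(x$average_degree, digits = 4), "\n")
  invisible(x)
}

#' Node overlap between two networks
#'
#' The Szymkiewicz–Simpson overlap coefficient of the two node-identity
#' sets: `|A intersect B| / min(|A|, |B|)`. Equals 1 whenever one node
#' set contains the other; 0 when either network is empty.
#'
#' @param a,b `knowledge_network` objects.
#' @return A number in `[0, 1]`.
#' @export
node_overlap <- function(a, b) {
  na <- nrow(a$nodes); nb <- nrow(b$nodes)
  if (na == 0 || nb == 0) return(0)
  length(intersect(a$nodes$id, b$nodes$id)) / min(na, nb)
}

#' Find contradictory pairs
#'
#' An ordered node pair (u, v) is contradictory when the network carries
#' at least one increasing and at least one decreasing causal edge from u
#' to v. Direct and indirect causal forms are pooled by sign, and edge
#' qualifiers such as activity are ignored when pairing, so e.g. an
#' assertion that a protein increases the transcriptional activity of a
#' target contradicts one that it decreases it.
#'
#' @param network A `knowledge_network`.
#' @return A tibble with columns `source`, `target`, `n_positive`,
#'   `n_negative`, `edge_indices` (list of row indices into the edge
#'   table), ordered by (source, target).
#' @export
find_contradictory_pairs <- function(network) {
  e <- network$edges
  causal <- which(e$sign != 0L)
  if (length(causal) == 0) {
    return(tibble(source = character(), target = character(),
                  n_positive = integer(), n_negative = integer(),
                  edge_indices = list()))
  }
  tibble(
    source = e$source[causal], target = e$target[causal],
    sign = e$sign[causal], idx = causal
  ) |>
    group_by(.data$source, .data$target) |>
    summarise(
      n_positive = sum(.data$sign > 0L),
      n_negative = sum(.data$sign < 0L),
      edge_indices = list(.data$idx),
      .groups = "drop"
    ) |>
    filter(.data$n_positive > 0L & .data$n_negative > 0L) |>
    arrange(.data$source, .data$target)
}

#' Find inconsistent negative-correlation triples
#'
#' Unordered node triples \{a, b, c\} in which each of the three pairs
#' carries at least one `negativeCorrelation` edge (in either stored
#' direction). Such a triangle is sign-inconsistent as a correlation
#' cycle. Each triple is reported once, in lexicographic node order.
#'
#' @param network A `knowledge_network`.
#' @return A tibble with columns `a`, `b`, `c` (sorted node ids).
#' @export
find_inconsistent_negative_correlation_triples <- function(network) {
  e <- network$edges[network$edges$relation == "negativeCorrelation", , drop = FALSE]
  out <- tibble(a = character(), b = character(), c = character())
  if (nrow(e) == 0) return(out)
  e <- e[e$source != e$target, , drop = FALSE]
  # undirected adjacency on negative correlations
  neigh <- split(c(e$target, e$source), c(e$source, e$target))
  neigh <- lapply(neigh, unique)
  triples <- character(0)
  rows <- list()
  for (a in names(neigh)) {
    nb <- neigh[[a]]
    if (length(nb) < 2) next
    for (b in nb) {
      for (cc in neigh[[b]]) {
        if (cc == a || !cc %in% nb) next
        trio <- sort(c(a, b, cc))
        key <- paste(trio, collapse = "\r")
        if (!key %in% triples) {
          triples <- c(triples, key)
          rows[[length(rows) + 1L]] <- tibble(a = trio[1], b = trio[2], c = trio[3])
        }
      }
    }
  }
  if (length(rows) == 0) return(out)
  arrange(bind_rows(rows), .data$a, .data$b, .data$c)
}

#' Search a network for registered motifs
#'
#' The two built-in biogrammar motifs are `contradictory_pair` and
#' `negative_correlation_triple`; additional motif predicates can be
#' supplied as functions taking a network and returning a tibble of
#' occurrences.
#'
#' @param network A `knowledge_network`.
#' @param motifs Named list of motif finder functions; defaults to the
#'   two built-in motifs.
#' @return Named list of occurrence tibbles.
#' @export
find_motifs <- function(network, motifs = NULL) {
  motifs <- motifs %||% list(
    contradictory_pair = find_contradictory_pairs,
    negative_correlation_triple = find_inconsistent_negative_correlation_triples
  )
  lapply(motifs, function(f) f(network))
}
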