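# Omics mapping and sign-aware heat diffusion.
#
# Scores (e.g. log2 fold changes) are annotated to nodes as initial
# heat and propagated along causal edges over synchronous iterations.
# When heat crosses a decreasing edge its sign is flipped, so mixed
# polarity aggregates correctly at a node. Heat is read out at
# biological-process nodes, which are typically sinks of the causal
# graph.

#' Read an omics score table
#'
#' TSV with required header columns `namespace`, `name`, `score`
#' (signed, e.g. log2 fold change).
#'
#' @param path File path.
#' @param experiment Optional experiment label attached to the table.
#' @return A tibble with columns `namespace`, `name`, `score`.
#' @export
read_omics_tsv <- function(path, experiment = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("namespace", "name", "score")
  if (!all(required %in% names(tab))) {
    stop("omics table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[required]
  attr(tab, "experiment") <- experiment %||% basename(path)
  tab
}

#' Map omics scores onto a network
#'
#' Assigns each row's score as the initial heat of the gene node with a
#' matching (namespace, name) — namespace keywords case-insensitive,
#' names case-sensitive. Unmatched rows and unmapped gene nodes are
#' reported. Networks are typically pre-processed with
#' [collapse_to_genes()] first so every measured entity is a gene node.
#'
#' @param network A `knowledge_network`.
#' @param omics Tibble with columns `namespace`, `name`, `score`; rows
#'   unique per (namespace, name), scores finite.
#' @return A `heat_state`: list with `h0` (named vector over all node
#'   ids, 0 where unmapped), `unmatched_rows` (tibble), `mapped_count`,
#'   `unmapped_nodes` (gene node ids without scores).
#' @export
map_scores <- function(network, omics) {
  if (is.null(omics) || nrow(omics) == 0) {
    stop("omics table is empty", call. = FALSE)
  }
  stopifnot(all(c("namespace", "name", "score") %in% names(omics)))
  if (anyDuplicated(paste(tolower(omics$namespace), omics$name))) {
    stop("omics table has duplicate (namespace, name) rows", call. = FALSE)
  }
  if (!all(is.finite(omics$score))) stop("omics scores must be finite", call. = FALSE)
  nodes <- network$nodes
  h0 <- setNames(rep(0, nrow(nodes)), nodes$id)
  genes <- nodes[nodes$func == "gene", , drop = FALSE]
  gene_key <- paste(tolower(genes$namespace), genes$name, sep = "\r")
  row_key <- paste(tolower(omics$namespace), omics$name, sep = "\r")
  hit <- match(row_key, gene_key)
  matched <- !is.na(hit)
  h0[genes$id[hit[matched]]] <- omics$score[matched]
  structure(
    list(
      h0 = h0,
      unmatched_rows = omics[!matched, , drop = FALSE],
      mapped_count = sum(matched),
      unmapped_nodes = setdiff(genes$id, genes$id[hit[matched]]),
      experiment = attr(omics, "experiment") %||% ""
    ),
    class = "heat_state"
  )
}

#' Sign-aware heat diffusion over the causal subgraph
#'
#' Operates on causal edges only. Parallel causal edges between an
#' ordered node pair are collapsed to their net sign (sum of signs,
#' clamped to -1/0/+1); pairs whose signs cancel are dropped and
#' reported. Each synchronous iteration, every non-sink node forwards
#' its entire working heat, split equally over its out-neighbors and
#' multiplied by the edge sign — crossing a decreasing edge flips the
#' sign. Sink nodes (no outgoing causal edges) absorb incoming heat.
#' Iteration stops when the total working heat magnitude falls below
#' `tolerance` or after `max_iterations` (guaranteeing termination on
#' cyclic graphs).
#'
#' @param network A nonempty `knowledge_network`.
#' @param state A `heat_state` from [map_scores()], or a named numeric
#'   vector of initial heats over node ids.
#' @param max_iterations Iteration cap.
#' @param tolerance Stop when total un-absorbed |heat| drops below this.
#' @return A `diffusion_result`: list with `final_heat` (named vector:
#'   absorbed heat on sinks, residual working heat on non-sinks),
#'   `absorbed` (sinks only), `iterations_run`, `residual` (total
#'   un-absorbed |heat| at stop), `dropped_contradictory_edges` (tibble
#'   of net-sign-zero pairs).
#' @export
diffuse <- function(network, state, max_iterations = 100L, tolerance = 1e-8) {
  stopifnot(inherits(network, "knowledge_network"))
  if (nrow(network$nodes) == 0) stop("network is empty", call. = FALSE)
  h0 <- if (inherits(state, "heat_state")) state$h0 else state
  ids <- network$nodes$id
  heat <- setNames(rep(0, length(ids)), ids)
  heat[intersect(names(h0), ids)] <- h0[intersect(names(h0), ids)]

  e <- network$edges[network$edges$sign != 0L, , drop = FALSE]
  net_sign <- tibble(source = e$source, target = e$target, sign = e$sign) |>
    group_by(.data$source, .data$target) |>
    summarise(sigma = sign(sum(.data$sign)), .groups = "drop")
  dropped <- net_sign[net_sign$sigma == 0, c("source", "target")]
  arcs <- net_sign[net_sign$sigma != 0, , drop = FALSE]

  out_count <- table(arcs$source)
  outdeg <- setNames(rep(0L, length(ids)), ids)
  outdeg[names(out_count)] <- as.integer(out_count)
  is_sink <- outdeg == 0L

  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  # column-stochastic-in-magnitude transition: M[v, u] = sigma / outdeg(u)
  M <- matrix(0, n, n)
  if (nrow(arcs) > 0) {
    M[cbind(idx[arcs$target], idx[arcs$source])] <-
      arcs$sigma / outdeg[arcs$source]
  }

  absorbed <- setNames(rep(0, n), ids)
  working <- heat
  absorbed[is_sink] <- working[is_sink]
  working[is_sink] <- 0

  iterations <- 0L
  while (iterations < max_iterations && sum(abs(working)) >= tolerance) {
    incoming <- as.numeric(M %*% working)
    names(incoming) <- ids
    absorbed[is_sink] <- absorbed[is_sink] + incoming[is_sink]
    working <- incoming
    working[is_sink] <- 0
    iterations <- iterations + 1L
  }

  final_heat <- working
  final_heat[is_sink] <- absorbed[is_sink]
  structure(
    list(
      final_heat = final_heat,
      absorbed = absorbed[is_sink],
      iterations_run = iterations,
      residual = sum(abs(working)),
      dropped_contradictory_edges = dropped
    ),
    class = "diffusion_result"
  )
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat("<diffusion_result> iterations:", x$iterations_run,
      " residual:", format(x$residual, digits = 4), "\n")
  cat("  sinks absorbed:", length(x$absorbed),
      " dropped contradictory pairs:", nrow(x$dropped_contradictory_edges), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.diffusion_result <- function(x, ...) {
  tibble(node = names(x$final_heat), heat = unname(x$final_heat)) |>
    arrange(desc(abs(.data$heat)))
}

#' @exportS3Method generics::glance
glance.diffusion_result <- function(x, ...) {
  tibble(iterations_run = x$iterations_run, residual = x$residual,
         total_absorbed = sum(x$absorbed),
         dropped_pairs = nrow(x$dropped_contradictory_edges))
}

#' Final heats on biological processes
#'
#' Restricts the diffusion result to nodes with function `bioprocess`,
#' the readout used to interpret which processes are dysregulated.
#'
#' @param result A `diffusion_result`.
#' @param network The network the diffusion ran on.
#' @return A tibble with columns `node`, `name`, `heat`, sorted by
#'   absolute heat descending.
#' @export
process_heats <- function(result, network) {
  bp <- network$nodes[network$nodes$func == "bioprocess", , drop = FALSE]
  tibble(node = bp$id, name = bp$name,
         heat = unname(result$final_heat[bp$id])) |>
    arrange(desc(abs(.data$heat)))
}

#' Cluster biological-process heat trajectories
#'
#' Collects the per-experiment heats of each biological process into a
#' trajectory vector (missing entries 0) and partitions the processes
#' with K-means (Euclidean distance, 10 restarts, deterministic given
#' `seed`). With fewer distinct trajectories than `k`, that many
#' clusters are returned without error.
#'
#' @param heats List of per-experiment heat tables: either named numeric
#'   vectors (node -> heat) or tibbles with columns `node`, `heat`, in
#'   experiment order.
#' @param k Number of clusters (the application workflow uses 5).
#' @param seed Integer seed fixing initialization.
#' @param standardize Scale each experiment column to unit variance
#'   before clustering (off by default: raw heats are clustered).
#' @return A `heat_trajectories` object: list with `trajectories`
#'   (tibble: `node`, one column per experiment, `cluster` in 0..k-1)
#'   and `k`.
#' @export
cluster_trajectories <- function(heats, k = 5L, seed = 0L, standardize = FALSE) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (length(heats) < 2) stop("need at least 2 experiments", call. = FALSE)
  as_vec <- function(h) {
    if (is.data.frame(h)) setNames(h$heat, h$node) else h
  }
  vecs <- lapply(heats, as_vec)
  labels <- names(heats) %||% paste0("experiment_", seq_along(heats))
  labels[labels == ""] <- paste0("experiment_", which(labels == ""))
  all_nodes <- sort(unique(unlist(lapply(vecs, names))))
  mat <- vapply(vecs, function(v) {
    out <- setNames(rep(0, length(all_nodes)), all_nodes)
    out[intersect(names(v), all_nodes)] <- v[intersect(names(v), all_nodes)]
    out
  }, numeric(length(all_nodes)))
  if (length(all_nodes) == 1L) mat <- matrix(mat, nrow = 1, dimnames = list(all_nodes, labels))
  colnames(mat) <- labels
  X <- mat
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  row_key <- apply(round(X, 12), 1, paste, collapse = "\r")
  n_distinct <- length(unique(row_key))
  k_eff <- min(k, n_distinct)
  cluster <- if (k_eff <= 1L) {
    rep(1L, nrow(X))
  } else if (k_eff == n_distinct) {
    # every distinct trajectory is its own cluster
    match(row_key, unique(row_key))
  } else {
    fit <- withr::with_seed(seed, kmeans(X, centers = k_eff, nstart = 10L,
                                         iter.max = 100L))
    fit$cluster
  }
  trajectories <- as_tibble(mat)
  trajectories <- bind_rows(trajectories)
  trajectories <- mutate(trajectories, node = all_nodes, .before = 1)
  trajectories$cluster <- as.integer(cluster) - 1L
  structure(list(trajectories = trajectories, k = k_eff),
            class = "heat_trajectories")
}

#' @export
print.heat_trajectories <- function(x, ...) {
  cat("<heat_trajectories>", nrow(x$trajectories), "nodes,",
      x$k, "clusters\n")
  invisible(x)
}

#' Size nodes by a topological or data-driven metric
#'
#' Provides the node sizes used when rendering analysis results:
#' `degree` is the multigraph in+out degree, `betweenness` is standard
#' shortest-path betweenness on the directed simple graph (symmetric
#' edges both ways), and `heat` is the absolute final heat of a
#' diffusion result.
#'
#' @param network A `knowledge_network`.
#' @param metric One of `"degree"`, `"betweenness"`, `"heat"`.
#' @param result `diffusion_result`, required for `metric = "heat"`.
#' @return Named nonnegative numeric vector over node ids.
#' @export
size_by_metric <- function(network, metric = c("degree", "betweenness", "heat"),
                           result = NULL) {
  metric <- match.arg(metric)
  ids <- network$nodes$id
  switch(metric,
    degree = {
      cnt <- table(c(network$edges$source, network$edges$target))
      out <- setNames(rep(0, length(ids)), ids)
      out[names(cnt)] <- as.numeric(cnt)
      out
    },
    betweenness = {
      g <- as_belkit_igraph(network, simple = TRUE)
      btw <- igraph::betweenness(g, directed = TRUE)
      btw[ids]
    },
    heat = {
      if (is.null(result)) stop("metric 'heat' needs a diffusion result", call. = FALSE)
      out <- setNames(rep(0, length(ids)), ids)
      common <- intersect(names(result$final_heat), ids)
      out[common] <- abs(result$final_heat[common])
      out
    }
  )
}

#' Write a bioprocess trajectory table to TSV
#'
#' Columns: `bioprocess`, one column per experiment, `cluster`.
#'
#' @param trajectories A `heat_trajectories` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_tsv <- function(trajectories, path) {
  tab <- trajectories$trajectories
  names(tab)[names(tab) == "node"] <- "bioprocess"
  readr::write_tsv(tab, path)
  invisible(path)
}
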