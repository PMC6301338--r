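# Brute-force oracles, independent of the package's igraph-backed
# implementations: plain adjacency-list BFS/DFS and set algebra over the
# edge tables.

# undirected adjacency over all edges (direction ignored entirely)
oracle_undirected_adj <- function(network) {
  e <- network$edges
  adj <- lapply(setNames(network$nodes$id, network$nodes$id), function(x) character(0))
  for (i in seq_len(nrow(e))) {
    adj[[e$source[i]]] <- c(adj[[e$source[i]]], e$target[i])
    adj[[e$target[i]]] <- c(adj[[e$target[i]]], e$source[i])
  }
  lapply(adj, unique)
}

# directed adjacency; symmetric edges traversable both ways
oracle_directed_adj <- function(network, causal_only = FALSE) {
  e <- network$edges
  if (causal_only) e <- e[e$sign != 0L, , drop = FALSE]
  adj <- lapply(setNames(network$nodes$id, network$nodes$id), function(x) character(0))
  for (i in seq_len(nrow(e))) {
    adj[[e$source[i]]] <- c(adj[[e$source[i]]], e$target[i])
    if (e$symmetric[i]) adj[[e$target[i]]] <- c(adj[[e$target[i]]], e$source[i])
  }
  lapply(adj, unique)
}

oracle_bfs_levels <- function(adj, sources, max_depth = Inf) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier) > 0 && d < max_depth) {
    d <- d + 1
    nxt <- character(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (dist[[v]] > d) {
          dist[[v]] <- d
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_neighbors_nodes <- function(network, seeds, n) {
  dist <- oracle_bfs_levels(oracle_undirected_adj(network), seeds, max_depth = n)
  names(dist)[dist <= n]
}

oracle_upstream_nodes <- function(network, seeds) {
  e <- network$edges[network$edges$sign != 0L, , drop = FALSE]
  l1 <- union(seeds, e$source[e$target %in% seeds])
  union(l1, e$source[e$target %in% l1])
}

oracle_downstream_nodes <- function(network, seeds) {
  e <- network$edges[network$edges$sign != 0L, , drop = FALSE]
  l1 <- union(seeds, e$target[e$source %in% seeds])
  union(l1, e$target[e$source %in% l1])
}

# nodes on any shortest directed path between ordered seed pairs, via
# the distance identity d(s,v) + d(v,t) == d(s,t)
oracle_shortest_path_nodes <- function(network, seeds) {
  adj <- oracle_directed_adj(network)
  dist_from <- lapply(setNames(names(adj), names(adj)), function(v)
    oracle_bfs_levels(adj, v))
  keep <- seeds
  for (s in seeds) {
    for (t in setdiff(seeds, s)) {
      dst <- dist_from[[s]][[t]]
      if (!is.finite(dst)) next
      on_path <- names(adj)[vapply(names(adj), function(v) {
        is.finite(dist_from[[s]][[v]]) && is.finite(dist_from[[v]][[t]]) &&
          dist_from[[s]][[v]] + dist_from[[v]][[t]] == dst
      }, logical(1))]
      keep <- union(keep, on_path)
    }
  }
  keep
}

# nodes on simple directed paths of <= max_length edges between ordered
# seed pairs (depth-bounded DFS)
oracle_all_path_nodes <- function(network, seeds, max_length = 6L) {
  adj <- oracle_directed_adj(network)
  keep <- seeds
  walk <- function(v, t, path, depth) {
    if (v == t) {
      keep <<- union(keep, path)
      return(invisible())
    }
    if (depth == 0) return(invisible())
    for (w in adj[[v]]) {
      if (!w %in% path) walk(w, t, c(path, w), depth - 1L)
    }
  }
  for (s in seeds) {
    for (t in setdiff(seeds, s)) {
      walk(s, t, s, max_length)
    }
  }
  keep
}

# O(E^2)-style scan for contradictory ordered pairs
oracle_contradictory_pairs <- function(network) {
  e <- network$edges[network$edges$sign != 0L, , drop = FALSE]
  keys <- paste(e$source, e$target, sep = "\r")
  hits <- unique(keys[vapply(seq_along(keys), function(i) {
    any(keys == keys[i] & e$sign == -e$sign[i])
  }, logical(1))])
  out <- do.call(rbind, strsplit(sort(hits), "\r", fixed = TRUE))
  if (is.null(out)) {
    data.frame(source = character(), target = character())
  } else {
    data.frame(source = out[, 1], target = out[, 2])
  }
}

# O(n^3) enumeration of all-negative correlation triangles
oracle_neg_triangles <- function(network) {
  e <- network$edges[network$edges$relation == "negativeCorrelation" &
                       network$edges$source != network$edges$target, , drop = FALSE]
  pair_keys <- unique(c(paste(e$source, e$target, sep = "\r"),
                        paste(e$target, e$source, sep = "\r")))
  has_neg <- function(u, v) paste(u, v, sep = "\r") %in% pair_keys
  ids <- sort(network$nodes$id)
  out <- list()
  n <- length(ids)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (has_neg(ids[i], ids[j]) && has_neg(ids[j], ids[k]) &&
          has_neg(ids[k], ids[i])) {
        out[[length(out) + 1L]] <- data.frame(a = ids[i], b = ids[j], c = ids[k])
      }
    }
  }
  if (length(out) == 0) data.frame(a = character(), b = character(), c = character())
  else do.call(rbind, out)
}

# density by O(n^2) ordered-pair enumeration
oracle_density <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  if (n < 2) return(0)
  e <- network$edges[network$edges$source != network$edges$target, , drop = FALSE]
  connected <- 0L
  for (u in ids) for (v in ids) {
    if (u == v) next
    hit <- any(e$source == u & e$target == v) ||
      any(e$symmetric & e$source == v & e$target == u)
    if (hit) connected <- connected + 1L
  }
  connected / (n * (n - 1))
}

# exhaustive path-sum diffusion oracle for DAGs: absorbed heat at each
# sink is sum over nodes v and paths v -> sink of h0(v) * prod(sigma/outdeg)
oracle_dag_diffusion <- function(network, h0) {
  e <- network$edges[network$edges$sign != 0L, , drop = FALSE]
  agg <- aggregate(sign ~ source + target, data = as.data.frame(e[c("source", "target", "sign")]), sum)
  agg$sigma <- sign(agg$sign)
  agg <- agg[agg$sigma != 0, , drop = FALSE]
  outdeg <- table(agg$source)
  ids <- network$nodes$id
  sinks <- ids[!ids %in% agg$source]
  heat0 <- setNames(rep(0, length(ids)), ids)
  heat0[names(h0)] <- h0
  # path weight sums from every node to every sink, by memoized DFS
  weight_to <- function(v, t, memo) {
    key <- paste(v, t, sep = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (v == t) {
      memo[[key]] <- 1
      return(1)
    }
    rows <- which(agg$source == v)
    total <- 0
    if (length(rows) > 0) {
      d <- outdeg[[v]]
      for (r in rows) {
        total <- total + (agg$sigma[r] / d) * weight_to(agg$target[r], t, memo)
      }
    }
    memo[[key]] <- total
    total
  }
  memo <- new.env(parent = emptyenv())
  absorbed <- setNames(rep(0, length(sinks)), sinks)
  for (t in sinks) {
    for (v in ids) {
      if (heat0[[v]] != 0) {
        absorbed[[t]] <- absorbed[[t]] + heat0[[v]] * weight_to(v, t, memo)
      }
    }
  }
  absorbed
}

# betweenness by shortest-path counting (sigma identities), on the
# directed simple graph with symmetric edges both ways
oracle_betweenness <- function(network) {
  adj <- oracle_directed_adj(network)
  adj <- lapply(adj, unique)
  ids <- names(adj)
  dist_from <- lapply(setNames(ids, ids), function(v) oracle_bfs_levels(adj, v))
  # number of shortest paths s -> t by DP over distance levels
  sigma_from <- lapply(setNames(ids, ids), function(s) {
    d <- dist_from[[s]]
    sigma <- setNames(rep(0, length(ids)), ids)
    sigma[[s]] <- 1
    for (lev in sort(unique(d[is.finite(d) & d > 0]))) {
      for (v in ids[d == lev]) {
        preds <- ids[vapply(ids, function(u) v %in% adj[[u]] && d[[u]] == lev - 1,
                            logical(1))]
        sigma[[v]] <- sum(sigma[preds])
      }
    }
    sigma
  })
  btw <- setNames(rep(0, length(ids)), ids)
  for (s in ids) for (t in ids) {
    if (s == t) next
    dst <- dist_from[[s]][[t]]
    if (!is.finite(dst) || sigma_from[[s]][[t]] == 0) next
    for (v in setdiff(ids, c(s, t))) {
      dv <- dist_from[[s]][[v]]
      if (is.finite(dv) && is.finite(dist_from[[v]][[t]]) &&
          dv + dist_from[[v]][[t]] == dst) {
        btw[[v]] <- btw[[v]] +
          sigma_from[[s]][[v]] * sigma_from[[v]][[t]] / sigma_from[[s]][[t]]
      }
    }
  }
  btw
}
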