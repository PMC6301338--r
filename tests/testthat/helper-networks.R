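# In-code fixtures: hand-built and random knowledge networks.

rb1_e2f4_text <- paste(
  'SET DOCUMENT Name = "RB1 example"',
  'DEFINE NAMESPACE HGNC AS LIST {"RB1", "E2F4"}',
  'SET Citation = {"PubMed", "x", "1"}',
  'SET Evidence = "e"',
  "p(HGNC:RB1) increases act(p(HGNC:E2F4))",
  "p(HGNC:RB1) decreases act(p(HGNC:E2F4))",
  sep = "\n"
)

# a chain a -> b -> c -> d of increases edges over protein nodes
chain_network <- function(names = c("A", "B", "C", "D"), relation = "increases") {
  nodes <- node_spec_df("protein", "HGNC", names)
  edges <- tibble::tibble(
    source = nodes$id[-length(names)],
    target = nodes$id[-1],
    relation = relation
  )
  knowledge_network(nodes, edges)
}

pid <- function(names, ns = "HGNC") {
  vapply(names, function(nm) node_id(node_spec("protein", ns, nm)),
         character(1), USE.NAMES = FALSE)
}

# network from a compact edge description: data.frame(from, to, relation)
make_network <- function(spec, extra_nodes = character(0)) {
  names <- unique(c(spec$from, spec$to, extra_nodes))
  nodes <- node_spec_df("protein", "HGNC", names)
  ids <- setNames(nodes$id, names)
  edges <- tibble::tibble(
    source = unname(ids[spec$from]),
    target = unname(ids[spec$to]),
    relation = spec$relation
  )
  if (!is.null(spec$pmid)) {
    edges$citation_db <- "PubMed"
    edges$citation_ref <- as.character(spec$pmid)
  }
  knowledge_network(nodes, edges)
}

# random multigraph over protein nodes with citations, authors and
# annotations, for oracle-equivalence sweeps
random_network <- function(seed, n_nodes = 20L, n_edges = 35L,
                           relations = c("increases", "decreases",
                                         "directlyIncreases", "directlyDecreases",
                                         "association", "positiveCorrelation",
                                         "negativeCorrelation"),
                           n_pmids = 5L, n_authors = 4L) {
  withr::with_seed(seed, {
    nodes <- node_spec_df("protein", "HGNC", sprintf("N%d", seq_len(n_nodes)))
    authors_pool <- sprintf("Author %s", LETTERS[seq_len(n_authors)])
    src <- sample(nodes$id, n_edges, replace = TRUE)
    tgt <- sample(nodes$id, n_edges, replace = TRUE)
    keep <- src != tgt
    edges <- tibble::tibble(
      source = src[keep], target = tgt[keep],
      relation = sample(relations, sum(keep), replace = TRUE),
      citation_db = "PubMed",
      citation_ref = as.character(sample(seq_len(n_pmids), sum(keep), replace = TRUE)),
      citation_authors = lapply(seq_len(sum(keep)), function(i)
        sample(authors_pool, sample(1:2, 1))),
      annotations = lapply(seq_len(sum(keep)), function(i) {
        list(Tissue = sample(c("cortex", "hippocampus", "plasma"),
                             sample(1:2, 1)))
      })
    )
    knowledge_network(nodes, edges)
  })
}

# random DAG over proteins with a bioprocess sink layer, causal edges only
random_dag <- function(seed, n_nodes = 10L, p_edge = 0.3) {
  withr::with_seed(seed, {
    prot <- node_spec_df("protein", "HGNC", sprintf("D%d", seq_len(n_nodes)))
    bp <- node_spec_df("bioprocess", "GOBP", c("terminal process"))
    nodes <- dplyr::bind_rows(prot, bp)
    edges <- list()
    for (i in seq_len(n_nodes - 1)) {
      for (j in (i + 1):n_nodes) {
        if (stats::runif(1) < p_edge) {
          edges[[length(edges) + 1L]] <- tibble::tibble(
            source = prot$id[i], target = prot$id[j],
            relation = sample(c("increases", "decreases"), 1)
          )
        }
      }
    }
    # connect a few roots into the terminal process
    for (i in sample(seq_len(n_nodes), min(3L, n_nodes))) {
      edges[[length(edges) + 1L]] <- tibble::tibble(
        source = prot$id[i], target = bp$id[1],
        relation = sample(c("increases", "decreases"), 1)
      )
    }
    knowledge_network(nodes, dplyr::bind_rows(edges))
  })
}

random_h0 <- function(network, seed, n_sources = 3L) {
  withr::with_seed(seed, {
    ids <- sample(network$nodes$id, min(n_sources, nrow(network$nodes)))
    setNames(stats::runif(length(ids), -2, 2), ids)
  })
}

expect_same_nodeset <- function(network, ids) {
  expect_setequal(network$nodes$id, ids)
}
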