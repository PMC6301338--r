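test_that("neighbor seeding follows undirected distance", {
  net <- chain_network()
  got <- seed_neighbors(net, pid("A"), n = 1)
  expect_same_nodeset(got, pid(c("A", "B")))
  # saturating at the diameter returns the whole component
  full <- seed_neighbors(net, pid("A"), n = 3)
  expect_same_nodeset(full, net$nodes$id)
  # distance ignores direction: seeding at the sink also reaches back
  expect_same_nodeset(seed_neighbors(net, pid("D"), n = 1), pid(c("C", "D")))
  expect_error(seed_neighbors(net, pid("NOPE")), "NOPE")
})

test_that("upstream/downstream use two causal layers and induce causal edges", {
  net <- chain_network()
  up <- seed_upstream(net, pid("D"))
  expect_same_nodeset(up, pid(c("B", "C", "D")))
  expect_equal(nrow(up$edges), 2L)

  down <- seed_downstream(net, pid("A"))
  expect_same_nodeset(down, pid(c("A", "B", "C")))

  # seeding at a source with no in-edges keeps just the seed
  lonely <- seed_upstream(net, pid("A"))
  expect_same_nodeset(lonely, pid("A"))
  expect_equal(nrow(lonely$edges), 0L)

  # correlative edges are not causal and never traversed
  corr <- make_network(data.frame(from = "A", to = "B",
                                  relation = "positiveCorrelation"))
  expect_same_nodeset(seed_upstream(corr, pid("B")), pid("B"))
})

test_that("shortest-path seeding keeps only nodes on shortest paths", {
  net <- make_network(data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                                 relation = "increases"))
  got <- seed_shortest_paths(net, pid(c("A", "C")))
  expect_same_nodeset(got, pid(c("A", "C")))  # direct edge wins

  disconnected <- make_network(data.frame(from = c("A", "C"), to = c("B", "D"),
                                          relation = "increases"))
  iso <- seed_shortest_paths(disconnected, pid(c("A", "D")))
  expect_same_nodeset(iso, pid(c("A", "D")))
  expect_equal(nrow(iso$edges), 0L)
  expect_error(seed_shortest_paths(net, pid("A")), "at least 2")
})

test_that("all-paths seeding enumerates bounded simple paths", {
  net <- make_network(data.frame(
    from = c("A", "B", "A", "D", "E"),
    to = c("B", "C", "D", "E", "C"),
    relation = "increases"
  ))
  got <- seed_all_paths(net, pid(c("A", "C")))
  expect_same_nodeset(got, pid(c("A", "B", "C", "D", "E")))
  short <- seed_all_paths(net, pid(c("A", "C")), max_length = 1)
  expect_same_nodeset(short, pid(c("A", "C")))
  expect_equal(nrow(short$edges), 0L)
})

test_that("provenance and author seeding filter edges by citation", {
  net <- make_network(data.frame(
    from = c("A", "B", "C"), to = c("B", "C", "D"),
    relation = "increases", pmid = c("1", "2", "2")
  ))
  all_edges <- seed_provenance(net, c("1", "2"))
  expect_equal(nrow(all_edges$edges), 3L)
  expect_equal(nrow(seed_provenance(net, "99")$nodes), 0L)
  one <- seed_provenance(net, "2")
  expect_same_nodeset(one, pid(c("B", "C", "D")))

  authored <- net
  authored$edges$citation_authors <- list("Ada Curator",
                                          c("Boris Kurator", "Ada Curator"),
                                          "Carla Annotator")
  got <- seed_authors(authored, "ada curator")
  expect_equal(nrow(got$edges), 2L)
  expect_equal(nrow(seed_authors(authored, "Nobody")$edges), 0L)
})

test_that("annotation seeding is OR within a key and AND across keys", {
  net <- make_network(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
                                 relation = "increases"))
  net$edges$annotations <- list(
    list(Subgraph = "GABA subgraph", Tissue = "cortex"),
    list(Subgraph = "Notch signaling subgraph"),
    list(Subgraph = "GABA subgraph", Tissue = "plasma")
  )
  both_subgraphs <- seed_annotations(net, list(
    Subgraph = c("GABA subgraph", "Notch signaling subgraph")
  ))
  expect_equal(nrow(both_subgraphs$edges), 3L)

  conj <- seed_annotations(net, list(Subgraph = "GABA subgraph",
                                     Tissue = "cortex"))
  expect_equal(nrow(conj$edges), 1L)

  # two-key filter equals the edge intersection of single-key filters
  k1 <- seed_annotations(net, list(Subgraph = "GABA subgraph"))
  k2 <- seed_annotations(net, list(Tissue = c("cortex", "plasma")))
  expect_setequal(edge_keys(conj),
                  intersect(edge_keys(seed_annotations(net, list(Tissue = "cortex"))),
                            edge_keys(k1)))
  expect_equal(nrow(k1$edges), 2L)
  expect_equal(nrow(k2$edges), 2L)
})

test_that("seed methods agree with brute-force oracles on random networks", {
  for (seed in 1:25) {
    net <- random_network(seed, n_nodes = sample(8:20, 1), n_edges = 30L)
    seeds <- withr::with_seed(seed * 31L, sample(net$nodes$id, 3L))
    n_hop <- sample(1:3, 1)
    expect_setequal(seed_neighbors(net, seeds, n_hop)$nodes$id,
                    oracle_neighbors_nodes(net, seeds, n_hop))
    expect_setequal(seed_upstream(net, seeds)$nodes$id,
                    oracle_upstream_nodes(net, seeds))
    expect_setequal(seed_downstream(net, seeds)$nodes$id,
                    oracle_downstream_nodes(net, seeds))
    expect_setequal(seed_shortest_paths(net, seeds[1:2])$nodes$id,
                    oracle_shortest_path_nodes(net, seeds[1:2]))
    expect_setequal(seed_all_paths(net, seeds[1:2], max_length = 4)$nodes$id,
                    oracle_all_path_nodes(net, seeds[1:2], 4L))
  }
})

test_that("upstream is downstream on the edge-reversed network", {
  for (seed in 1:10) {
    net <- random_network(seed, n_nodes = 15L, n_edges = 30L)
    rev <- net
    rev$edges$source <- net$edges$target
    rev$edges$target <- net$edges$source
    seeds <- withr::with_seed(seed, sample(net$nodes$id, 2L))
    expect_setequal(seed_upstream(net, seeds)$nodes$id,
                    seed_downstream(rev, seeds)$nodes$id)
  }
})

test_that("seeding with every node via neighbors returns the assembly", {
  net <- random_network(3, n_nodes = 12L, n_edges = 25L)
  got <- seed_neighbors(net, net$nodes$id, n = 1)
  expect_setequal(got$nodes$id, net$nodes$id)
  expect_setequal(edge_keys(got), edge_keys(net))
})

test_that("identity queries return the input network byte-identically", {
  net <- random_network(9, n_nodes = 10L, n_edges = 20L)
  q <- bel_query("main")
  out <- run_query(q, list(main = net))
  expect_identical(write_network_json(out), write_network_json(net))
})

test_that("multiple seeds union their subnetworks", {
  net <- make_network(data.frame(
    from = c("A", "B", "X"), to = c("B", "C", "Y"),
    relation = "increases", pmid = c("1", "1", "7")
  ))
  q <- bel_query("main", seeds = list(
    list(method = "provenance", payload = list(pmids = "7")),
    list(method = "neighbors", payload = list(nodes = pid("A"), n = 1))
  ))
  got <- run_query(q, list(main = net))
  manual <- belkit:::union_networks(list(
    seed_provenance(net, "7"),
    seed_neighbors(net, pid("A"), 1)
  ))
  expect_setequal(got$nodes$id, manual$nodes$id)
  expect_setequal(edge_keys(got), edge_keys(manual))
})

test_that("queries replay deterministically and validate before computing", {
  net <- random_network(4, n_nodes = 10L, n_edges = 20L)
  q <- bel_query("main",
                 seeds = list(list(method = "neighbors",
                                   payload = list(nodes = net$nodes$id[1], n = 2))),
                 pipeline = list(list(name = "extract_causal", args = list())))
  r1 <- write_network_json(run_query(q, list(main = net)))
  r2 <- write_network_json(run_query(q, list(main = net)))
  expect_identical(r1, r2)

  expect_error(run_query(bel_query("ghost"), list(main = net)), "unknown network")
  bad <- bel_query("main", pipeline = list(list(name = "no_such_transform")))
  expect_error(run_query(bad, list(main = net)), "unknown transformation")
})

test_that("query pipelines equal manual transformation chaining", {
  scen <- generate_scenario_corpus(seed = 3)
  net <- compile_network(parse_bel_document(scen$text))
  catalog <- list(corpus = net, families = scen$resource)
  q <- bel_query("corpus",
    seeds = list(list(method = "annotations",
                      payload = list(filters = list(Subgraph = "GABA subgraph")))),
    pipeline = list(
      list(name = "enrich_members", args = list(resource = "families")),
      list(name = "delete_namespace_nodes", args = list(namespaces = c("MGI", "RGD"))),
      list(name = "remove_pathologies", args = list()),
      list(name = "extract_causal", args = list())
    ))
  via_query <- run_query(q, catalog)
  manual <- seed_annotations(net, list(Subgraph = "GABA subgraph")) |>
    enrich_members(scen$resource) |>
    delete_namespace_nodes(c("MGI", "RGD")) |>
    remove_pathologies() |>
    extract_causal()
  expect_identical(write_network_json(via_query), write_network_json(manual))
})

test_that("undo unwinds pipeline steps, then seeds, down to the identity query", {
  q <- bel_query("main",
                 seeds = list(list(method = "provenance",
                                   payload = list(pmids = "1"))),
                 pipeline = list(list(name = "extract_causal", args = list()),
                                 list(name = "collapse_variants", args = list())))
  q1 <- undo_query(q)
  expect_equal(vapply(q1$pipeline, `[[`, "", "name"), "extract_causal")
  q2 <- undo_query(q1)
  expect_length(q2$pipeline, 0L)
  q3 <- undo_query(q2)
  expect_length(q3$seeds, 0L)
  expect_error(undo_query(q3), "nothing to undo")
})

test_that("query ids are stable content hashes", {
  q <- bel_query("main", seeds = list(
    list(method = "annotations",
         payload = list(filters = list(A = "x", B = "y")))
  ))
  expect_identical(query_id(q), query_id(q))

  permuted <- bel_query("main", seeds = list(
    list(method = "annotations",
         payload = list(filters = list(B = "y", A = "x")))
  ))
  expect_identical(query_id(q), query_id(permuted))

  different <- bel_query("main", seeds = list(
    list(method = "annotations",
         payload = list(filters = list(A = "x", B = "z")))
  ))
  expect_false(query_id(q) == query_id(different))
})

test_that("queries round-trip through JSON", {
  q <- bel_query(c("a", "b"),
                 seeds = list(list(method = "neighbors",
                                   payload = list(nodes = "p(HGNC:X)", n = 2))),
                 pipeline = list(list(name = "extract_causal", args = list())))
  q2 <- query_from_json(query_to_json(q))
  expect_identical(query_id(q), query_id(q2))
})
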