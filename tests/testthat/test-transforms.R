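test_that("extract_causal keeps signed edges and drops isolated nodes", {
  causal <- chain_network()
  expect_identical(write_network_json(extract_causal(causal)),
                   write_network_json(causal))

  corr <- make_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                  relation = "positiveCorrelation"))
  expect_equal(nrow(extract_causal(corr)$nodes), 0L)

  mixed <- make_network(data.frame(
    from = c("A", "B", "C"), to = c("B", "C", "D"),
    relation = c("increases", "association", "decreases")
  ))
  got <- extract_causal(mixed)
  expect_equal(nrow(got$edges), 2L)
  expect_setequal(got$edges$relation, c("increases", "decreases"))
})

test_that("remove_pathologies deletes pathology hubs but keeps isolated leaves", {
  nodes <- dplyr::bind_rows(
    node_spec_df("pathology", "MESH", "hub"),
    node_spec_df("protein", "HGNC", c("L1", "L2", "L3"))
  )
  edges <- tibble::tibble(source = nodes$id[2:4], target = nodes$id[1],
                          relation = "increases")
  star <- knowledge_network(nodes, edges)
  got <- remove_pathologies(star)
  expect_equal(nrow(got$edges), 0L)
  expect_setequal(got$nodes$id, pid(c("L1", "L2", "L3")))
  expect_identical(write_network_json(remove_pathologies(chain_network())),
                   write_network_json(chain_network()))
})

test_that("delete_namespace_nodes filters by namespace keyword", {
  net <- knowledge_network(
    dplyr::bind_rows(node_spec_df("protein", "HGNC", "H"),
                     node_spec_df("protein", "MGI", "M"),
                     node_spec_df("protein", "RGD", "R"))
  )
  expect_equal(nrow(delete_namespace_nodes(net, character(0))$nodes), 3L)
  expect_equal(nrow(delete_namespace_nodes(net, c("HGNC", "MGI", "RGD"))$nodes), 0L)
  got <- delete_namespace_nodes(net, c("MGI", "RGD"))
  expect_setequal(got$nodes$namespace, "HGNC")
})

test_that("enrich_protein_rna_origins adds the central dogma and is idempotent", {
  net <- knowledge_network(node_spec_df("protein", "HGNC", c("X", "Y")))
  got <- enrich_protein_rna_origins(net)
  expect_equal(nrow(got$nodes), 6L)   # +2 RNA +2 gene
  expect_equal(nrow(got$edges), 4L)   # 2 translatedTo + 2 transcribedTo
  expect_setequal(got$edges$relation, c("translatedTo", "transcribedTo"))
  twice <- enrich_protein_rna_origins(got)
  expect_identical(write_network_json(twice), write_network_json(got))

  # miRNA nodes get genes too
  mir <- knowledge_network(node_spec_df("mirna", "HGNC", "MIR1"))
  gotm <- enrich_protein_rna_origins(mir)
  expect_setequal(gotm$nodes$func, c("mirna", "gene"))
  expect_equal(gotm$edges$relation, "transcribedTo")
})

test_that("collapse_variants merges variant nodes into their base node", {
  nodes <- dplyr::bind_rows(
    node_spec_row(node_spec("protein", "HGNC", "X", "pmod(Ph)")),
    node_spec_df("protein", "HGNC", c("X", "Y"))
  )
  edges <- tibble::tibble(source = nodes$id[c(1, 2)], target = nodes$id[c(3, 3)],
                          relation = c("increases", "decreases"))
  net <- knowledge_network(nodes, edges)
  got <- collapse_variants(net)
  expect_equal(nrow(got$nodes), 2L)
  expect_equal(nrow(got$edges), 2L)
  expect_true(all(lengths(got$nodes$variants) == 0L))
  expect_identical(write_network_json(collapse_variants(chain_network())),
                   write_network_json(chain_network()))
})

test_that("collapse_to_genes quotients the central dogma onto gene nodes", {
  triple <- enrich_protein_rna_origins(
    knowledge_network(node_spec_df("protein", "HGNC", "X"))
  )
  got <- collapse_to_genes(triple)
  expect_equal(nrow(got$nodes), 1L)
  expect_equal(got$nodes$func, "gene")
  expect_equal(nrow(got$edges), 0L)

  genes_only <- knowledge_network(node_spec_df("gene", "HGNC", c("A", "B")))
  expect_identical(write_network_json(collapse_to_genes(genes_only)),
                   write_network_json(genes_only))

  # after enrichment, node count equals distinct (namespace, name) pairs
  corpus <- generate_corpus(corpus_spec(seed = 21, n_statements = 30L))
  net <- compile_network(parse_bel_document(corpus$text))
  enriched <- enrich_protein_rna_origins(collapse_variants(net))
  collapsed <- collapse_to_genes(enriched)
  expected <- nrow(unique(data.frame(
    central = enriched$nodes$func %in% c("gene", "rna", "mirna", "protein"),
    func = ifelse(enriched$nodes$func %in% c("gene", "rna", "mirna", "protein"),
                  "gene", enriched$nodes$func),
    namespace = enriched$nodes$namespace,
    name = enriched$nodes$name
  )))
  expect_equal(nrow(collapsed$nodes), expected)
  expect_identical(write_network_json(collapse_to_genes(collapsed)),
                   write_network_json(collapsed))
})

test_that("the full collapse pipeline leaves only non-transcript functions", {
  for (seed in 1:4) {
    corpus <- generate_corpus(corpus_spec(seed = seed, n_statements = 40L))
    net <- compile_network(parse_bel_document(corpus$text))
    out <- collapse_to_genes(collapse_variants(enrich_protein_rna_origins(net)))
    expect_true(all(out$nodes$func %in%
                      c("gene", "abundance", "complex", "composite",
                        "bioprocess", "pathology")))
  }
})

test_that("enrich_members adds one-hop members from the resource", {
  resource <- generate_family_resource(
    list(FamA = c("M1", "M2", "M3"), FamB = c("M4", "M5", "M6")), "HGNC"
  )
  expect_equal(nrow(resource$nodes), 8L)
  expect_equal(nrow(resource$edges), 6L)

  fam_id <- node_id(node_spec("complex", "HGNC", "FamA"))
  net <- knowledge_network(
    dplyr::bind_rows(node_spec_row(node_spec("complex", "HGNC", "FamA")),
                     node_spec_df("protein", "HGNC", "Other"))
  )
  got <- enrich_members(net, resource)
  expect_equal(nrow(got$nodes), 5L)  # FamA + Other + 3 members
  expect_equal(nrow(got$edges), 3L)
  expect_true(all(got$edges$source == fam_id))

  # resource families absent from the network do not fire
  expect_identical(write_network_json(enrich_members(chain_network(), resource)),
                   write_network_json(chain_network()))
  expect_identical(
    write_network_json(enrich_members(net, knowledge_network())),
    write_network_json(net)
  )
})

test_that("delete_node and delete_edge remove exactly one element", {
  net <- chain_network()
  smaller <- delete_node(net, pid("B"))
  expect_equal(nrow(smaller$nodes), 3L)
  expect_equal(nrow(smaller$edges), 1L)   # incident edges removed
  expect_error(delete_node(net, "p(HGNC:GHOST)"), "not in network")

  keys <- edge_keys(net)
  fewer <- delete_edge(net, keys[2])
  expect_equal(nrow(fewer$edges), 2L)
  expect_false(keys[2] %in% edge_keys(fewer))
  expect_error(delete_edge(net, "bogus"), "not in network")

  # degree bookkeeping after deletion
  deg <- size_by_metric(fewer, "degree")
  expect_equal(sum(deg), 2 * nrow(fewer$edges))
})

test_that("random_subsample is a deterministic induced subgraph", {
  net <- random_network(2, n_nodes = 30L, n_edges = 60L)
  expect_identical(write_network_json(random_subsample(net, 50L, seed = 1)),
                   write_network_json(net))
  s1 <- random_subsample(net, 10L, seed = 5)
  s2 <- random_subsample(net, 10L, seed = 5)
  expect_equal(nrow(s1$nodes), 10L)
  expect_identical(write_network_json(s1), write_network_json(s2))
  expect_true(all(edge_keys(s1) %in% edge_keys(net)))
})

test_that("highlight_selection selects without modifying", {
  net <- random_network(6, n_nodes = 10L, n_edges = 15L)
  before <- write_network_json(net)
  all_sel <- highlight_selection(net,
                                 node_predicate = function(n) rep(TRUE, nrow(n)),
                                 edge_predicate = function(e) rep(TRUE, nrow(e)))
  expect_equal(nrow(all_sel$nodes), nrow(net$nodes))
  expect_equal(nrow(all_sel$edges), nrow(net$edges))
  none <- highlight_selection(net)
  expect_equal(nrow(none$nodes), 0L)
  ns_sel <- highlight_selection(net, node_predicate = function(n) n$namespace == "HGNC")
  expect_equal(nrow(ns_sel$nodes), nrow(net$nodes))
  expect_identical(write_network_json(net), before)
})

test_that("transformations never modify their input in place", {
  net <- random_network(8, n_nodes = 12L, n_edges = 25L)
  before <- write_network_json(net)
  invisible(extract_causal(net))
  invisible(remove_pathologies(net))
  invisible(collapse_variants(net))
  invisible(collapse_to_genes(net))
  invisible(enrich_protein_rna_origins(net))
  expect_identical(write_network_json(net), before)
})

test_that("new transformations can be registered and invoked from queries", {
  reg <- register_transformation(
    transformation_registry(), "keep_first_edge",
    function(net, args, catalog) {
      net$edges <- net$edges[1, , drop = FALSE]
      belkit:::edges_subnetwork(net, TRUE)
    }
  )
  expect_error(register_transformation(reg, "keep_first_edge", identity),
               "already registered")
  q <- bel_query("main", pipeline = list(list(name = "keep_first_edge")))
  out <- run_query(q, list(main = chain_network()), registry = reg)
  expect_equal(nrow(out$edges), 1L)
})
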