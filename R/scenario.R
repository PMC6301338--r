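# End-to-end application workflow: assemble a disease-specific corpus,
# seed by curated-subgraph annotations, pre-process with the
# transformation pipeline, overlay staged differential-expression data,
# run sign-aware heat diffusion per stage, and cluster the
# biological-process heat trajectories with K-means.

#' Generate the staged-progression scenario corpus
#'
#' A synthetic corpus with the structure the staged analysis needs: four
#' curated candidate-mechanism subgraphs (annotation `Subgraph`), each
#' containing biological processes driven by dedicated upstream genes
#' via increasing causal statements; mouse/rat (MGI/RGD) statements,
#' pathology hubs, correlative edges and protein variants that the
#' pre-processing pipeline is expected to strip; and a protein family
#' whose members are added by membership enrichment. Each biological
#' process is assigned a trajectory archetype, inherited by its driver
#' genes, so diffusion followed by clustering can be checked against
#' planted truth.
#'
#' @param n_bp_per_subgraph Biological processes per subgraph.
#' @param n_drivers_per_bp Dedicated driver genes per process.
#' @param seed Integer seed fixing all randomness.
#' @return List with `text` (BEL script), `resource` (family
#'   membership network) and `truth` (tibble: bioprocess node id,
#'   archetype, driver gene names).
#' @export
generate_scenario_corpus <- function(n_bp_per_subgraph = 5L,
                                     n_drivers_per_bp = 3L, seed = 1L) {
  withr::with_seed(seed, {
    subgraphs <- c("Low density lipoprotein subgraph", "GABA subgraph",
                   "Notch signaling subgraph", "Reactive oxygen species subgraph")
    arch_names <- names(default_archetypes())
    n_bp <- length(subgraphs) * n_bp_per_subgraph
    bp_names <- sprintf("synthetic process %d", seq_len(n_bp))
    bp_subgraph <- rep(subgraphs, each = n_bp_per_subgraph)
    bp_arch <- arch_names[(seq_len(n_bp) - 1L) %% length(arch_names) + 1L]

    gene_names <- sprintf("SYNG%d", seq_len(n_bp * n_drivers_per_bp))
    driver_of <- split(gene_names, rep(seq_len(n_bp), each = n_drivers_per_bp))

    extra_genes <- sprintf("EXTRA%d", 1:6)
    family_members <- sprintf("FAM%d", 1:3)
    mgi <- sprintf("MouseG%d", 1:3)
    rgd <- sprintf("RatG%d", 1:3)
    pathology_terms <- c("synthetic pathology 1", "synthetic pathology 2")

    citations <- tibble(
      pmid = as.character(20000000L + 1:6),
      name = sprintf("Synthetic reference %d", 1:6)
    )

    lines <- c(
      'SET DOCUMENT Name = "Synthetic staged-progression corpus"',
      paste0("DEFINE NAMESPACE HGNC AS LIST {",
             paste(bel_quote(c(gene_names, extra_genes, family_members, "FAMILY1")),
                   collapse = ", "), "}"),
      paste0("DEFINE NAMESPACE GOBP AS LIST {",
             paste(bel_quote(bp_names), collapse = ", "), "}"),
      paste0("DEFINE NAMESPACE MESH AS LIST {",
             paste(bel_quote(pathology_terms), collapse = ", "), "}"),
      paste0("DEFINE NAMESPACE MGI AS LIST {", paste(bel_quote(mgi), collapse = ", "), "}"),
      paste0("DEFINE NAMESPACE RGD AS LIST {", paste(bel_quote(rgd), collapse = ", "), "}"),
      paste0("DEFINE ANNOTATION Subgraph AS LIST {",
             paste(bel_quote(subgraphs), collapse = ", "), "}")
    )
    stmt <- function(subject, relation, object, subgraph, evidence) {
      ci <- sample(nrow(citations), 1L)
      c("",
        paste0('SET Citation = {"PubMed", ', bel_quote(citations$name[ci]),
               ", ", bel_quote(citations$pmid[ci]), "}"),
        paste0("SET Evidence = ", bel_quote(evidence)),
        paste0("SET Subgraph = ", bel_quote(subgraph)),
        paste(subject, relation, object),
        "UNSET ALL")
    }
    k <- 0L
    for (i in seq_len(n_bp)) {
      bp_term <- paste0("bp(GOBP:", bel_quote(bp_names[i]), ")")
      for (gname in driver_of[[i]]) {
        k <- k + 1L
        # occasional variant form, collapsed away during pre-processing
        subj <- if (k %% 7L == 0L) {
          paste0("p(HGNC:", gname, ", pmod(Ph))")
        } else {
          paste0("p(HGNC:", gname, ")")
        }
        lines <- c(lines, stmt(subj, "increases", bp_term, bp_subgraph[i],
                               sprintf("Driver %s of process %d.", gname, i)))
      }
    }
    # family participation: the family node causally feeds one process
    lines <- c(lines, stmt("complex(HGNC:FAMILY1)", "increases",
                           paste0("bp(GOBP:", bel_quote(bp_names[1]), ")"),
                           bp_subgraph[1], "Family participation."))
    # content stripped by pre-processing: correlative, pathology, MGI/RGD
    for (i in seq_along(extra_genes)) {
      sg <- sample(subgraphs, 1L)
      lines <- c(lines,
        stmt(paste0("p(HGNC:", extra_genes[i], ")"), "positiveCorrelation",
             paste0("p(HGNC:", sample(setdiff(extra_genes, extra_genes[i]), 1L), ")"),
             sg, "Correlative filler."),
        stmt(paste0("p(HGNC:", extra_genes[i], ")"), "increases",
             paste0("path(MESH:", bel_quote(sample(pathology_terms, 1L)), ")"),
             sg, "Pathology filler."))
    }
    for (i in 1:3) {
      sg <- sample(subgraphs, 1L)
      lines <- c(lines,
        stmt(paste0("p(MGI:", mgi[i], ")"), "increases",
             paste0("p(HGNC:", sample(extra_genes, 1L), ")"), sg, "Mouse filler."),
        stmt(paste0("p(RGD:", rgd[i], ")"), "decreases",
             paste0("p(HGNC:", sample(extra_genes, 1L), ")"), sg, "Rat filler."))
    }

    resource <- generate_family_resource(list(FAMILY1 = family_members), "HGNC")
    truth <- tibble(
      bioprocess = vapply(bp_names, function(nm)
        node_id(node_spec("bioprocess", "GOBP", nm)), character(1)),
      archetype = bp_arch,
      subgraph = bp_subgraph,
      drivers = unname(driver_of)
    )
    list(text = paste(lines, collapse = "\n"), resource = resource, truth = truth)
  })
}

#' Run the staged-progression analysis workflow
#'
#' Executes the full pipeline on a synthetic staged corpus: compile,
#' seed by the four curated-subgraph annotations, enrich family
#' members, delete MGI/RGD nodes, remove pathologies, extract causal
#' edges, enrich protein/RNA origins, collapse variants, collapse to
#' genes; then generate three-stage differential-expression tables for
#' the driver genes, run heat diffusion per stage, and cluster the
#' biological-process heat trajectories with K-means.
#'
#' @param seed Integer seed fixing corpus generation, omics noise and
#'   clustering initialization.
#' @param k Number of K-means clusters.
#' @param noise_sd Omics noise standard deviation.
#' @return List with `network` (pre-processed network), `trajectories`
#'   (a `heat_trajectories`), `truth` (planted archetypes),
#'   `agreement` (cluster/archetype label agreement in [0, 1]) and
#'   `query` (the replayable `bel_query` that produced the network).
#' @export
run_staged_analysis <- function(seed = 1L, k = 5L, noise_sd = 0.25) {
  scen <- generate_scenario_corpus(seed = seed)
  doc <- parse_bel_document(scen$text)
  net <- compile_network(doc)
  catalog <- list(corpus = net, families = scen$resource)
  query <- bel_query(
    network_ids = "corpus",
    seeds = list(list(
      method = "annotations",
      payload = list(filters = list(Subgraph = unique(scen$truth$subgraph)))
    )),
    pipeline = list(
      list(name = "enrich_members", args = list(resource = "families")),
      list(name = "delete_namespace_nodes", args = list(namespaces = c("MGI", "RGD"))),
      list(name = "remove_pathologies", args = list()),
      list(name = "extract_causal", args = list()),
      list(name = "enrich_protein_rna_origins", args = list()),
      list(name = "collapse_variants", args = list()),
      list(name = "collapse_to_genes", args = list())
    )
  )
  processed <- run_query(query, catalog)

  genes <- tibble(
    namespace = "HGNC",
    name = unlist(scen$truth$drivers),
    archetype = rep(scen$truth$archetype,
                    vapply(scen$truth$drivers, length, integer(1)))
  )
  omics <- generate_staged_omics(genes, noise_sd = noise_sd, seed = seed)
  heats <- lapply(omics$tables, function(tab) {
    res <- diffuse(processed, map_scores(processed, tab))
    ph <- process_heats(res, processed)
    setNames(ph$heat, ph$node)
  })
  trajectories <- cluster_trajectories(heats, k = k, seed = seed)

  truth_arch <- setNames(scen$truth$archetype, scen$truth$bioprocess)
  traj <- trajectories$trajectories
  agreement <- cluster_label_agreement(
    setNames(traj$cluster, traj$node),
    truth_arch[traj$node]
  )
  list(network = processed, trajectories = trajectories,
       truth = scen$truth, agreement = agreement, query = query)
}

#' Agreement between a clustering and planted labels
#'
#' Maps each cluster to its modal planted label and returns the
#' fraction of items whose planted label matches their cluster's modal
#' label. Equals 1 when the clustering refines the planted partition.
#'
#' @param clusters Named or plain vector of cluster assignments.
#' @param truth Vector of planted labels, aligned with `clusters`.
#' @return A number in `[0, 1]`.
#' @export
cluster_label_agreement <- function(clusters, truth) {
  stopifnot(length(clusters) == length(truth))
  modal <- tapply(as.character(truth), clusters, function(x) {
    names(sort(table(x), decreasing = TRUE))[1]
  })
  mean(modal[as.character(clusters)] == as.character(truth))
}
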