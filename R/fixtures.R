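# Deterministic generators of synthetic BEL corpora, membership
# resource networks and staged omics tables, so that every module is
# testable offline. Each generator returns a ground-truth ledger as a
# first-class output: motif, seeding and diffusion tests compare against
# planted truth rather than re-derived truth.

#' Specification of a synthetic BEL corpus
#'
#' @param n_statements Number of random relational statements in
#'   addition to the planted motifs.
#' @param n_genes Number of gene symbols in the primary namespace.
#' @param n_bioprocesses,n_pathologies Number of biological-process and
#'   pathology terms.
#' @param n_foreign_genes Gene symbols in each of the MGI and RGD
#'   (mouse/rat) namespaces.
#' @param n_citations Size of the synthetic PubMed citation pool.
#' @param n_contradictions Contradictory pairs to plant (same ordered
#'   node pair with both increasing and decreasing statements).
#' @param n_neg_triangles All-negative correlation triangles to plant.
#' @param relation_weights Named sampling weights over the relation
#'   vocabulary used for random statements.
#' @param annotations Named list of annotation keyword -> allowed values;
#'   each statement gets one value per keyword.
#' @param p_variant Probability that a protein subject carries a
#'   phosphorylation variant.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_statements = 60L, n_genes = 25L,
                        n_bioprocesses = 5L, n_pathologies = 2L,
                        n_foreign_genes = 0L, n_citations = 8L,
                        n_contradictions = 2L, n_neg_triangles = 1L,
                        relation_weights = c(increases = 4, directlyIncreases = 2,
                                             decreases = 3, directlyDecreases = 1,
                                             association = 1,
                                             positiveCorrelation = 1,
                                             negativeCorrelation = 1),
                        annotations = list(
                          CellLine = c("SH-SY5Y", "HEK293", "U87"),
                          Subgraph = c("Low density lipoprotein subgraph",
                                       "GABA subgraph",
                                       "Notch signaling subgraph",
                                       "Reactive oxygen species subgraph")
                        ),
                        p_variant = 0.1, seed = 1L) {
  stopifnot(n_genes >= 3, n_statements >= 0, n_citations >= 1,
            all(names(relation_weights) %in% RELATIONS))
  structure(
    list(n_statements = n_statements, n_genes = n_genes,
         n_bioprocesses = n_bioprocesses, n_pathologies = n_pathologies,
         n_foreign_genes = n_foreign_genes, n_citations = n_citations,
         n_contradictions = n_contradictions, n_neg_triangles = n_neg_triangles,
         relation_weights = relation_weights, annotations = annotations,
         p_variant = p_variant, seed = seed),
    class = "corpus_spec"
  )
}

#' Generate a synthetic BEL corpus with a ground-truth ledger
#'
#' Emits a valid BEL script (inline namespace definitions, one SET block
#' per statement) together with a ledger recording the planted truth:
#' statement count, expected node ids, contradictory pairs, negative
#' correlation triangles, and the citation/author/annotation assignment
#' of every statement. Random statements that would accidentally create
#' an unplanted contradiction or all-negative triangle are rejected and
#' resampled, so the ledger is exact. Deterministic given the spec seed.
#'
#' @param spec A [corpus_spec()].
#' @return List with `text` (BEL script) and `ledger`.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  withr::with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  genes <- sprintf("SYNG%d", seq_len(spec$n_genes))
  bps <- sprintf("synthetic process %d", seq_len(spec$n_bioprocesses))
  paths <- sprintf("synthetic pathology %d", seq_len(spec$n_pathologies))
  mgi <- if (spec$n_foreign_genes > 0) sprintf("MouseG%d", seq_len(spec$n_foreign_genes)) else character(0)
  rgd <- if (spec$n_foreign_genes > 0) sprintf("RatG%d", seq_len(spec$n_foreign_genes)) else character(0)

  citations <- tibble(
    pmid = as.character(10000000L + seq_len(spec$n_citations)),
    name = sprintf("Synthetic reference %d", seq_len(spec$n_citations)),
    authors = lapply(seq_len(spec$n_citations), function(i) {
      pool <- c("Ada Curator", "Boris Kurator", "Carla Annotator",
                "Deniz Reviewer", "Elio Modeler")
      sort(sample(pool, sample(1:3, 1)))
    })
  )

  # statement assembly state, used to veto accidental motifs
  causal_sign <- new.env(parent = emptyenv())   # "u|v" -> set of signs seen
  neg_adj <- new.env(parent = emptyenv())       # gene -> neighbors by negCorr

  protein <- function(name, ns = "HGNC", variants = character()) {
    node_spec("protein", ns, name, variants)
  }

  statements <- list()
  add_statement <- function(subject, relation, object,
                            subject_activity = FALSE, object_activity = FALSE) {
    ci <- sample(nrow(citations), 1L)
    ann <- lapply(spec$annotations, function(vals) sample(vals, 1L))
    statements[[length(statements) + 1L]] <<- list(
      subject = subject, relation = relation, object = object,
      subject_activity = subject_activity, object_activity = object_activity,
      citation = citations[ci, ],
      evidence = sprintf("Synthetic evidence sentence %d.", length(statements) + 1L),
      annotations = ann
    )
  }

  note_causal <- function(u, v, s) {
    key <- paste(u, v, sep = "|")
    causal_sign[[key]] <- union(causal_sign[[key]], s)
  }
  would_contradict <- function(u, v, s) {
    key <- paste(u, v, sep = "|")
    any((causal_sign[[key]] %||% integer(0)) == -s)
  }
  note_neg <- function(u, v) {
    neg_adj[[u]] <- union(neg_adj[[u]] %||% character(0), v)
    neg_adj[[v]] <- union(neg_adj[[v]] %||% character(0), u)
  }
  would_close_triangle <- function(u, v) {
    length(intersect(neg_adj[[u]] %||% character(0),
                     neg_adj[[v]] %||% character(0))) > 0
  }

  # planted contradictory pairs
  planted_pairs <- list()
  if (spec$n_contradictions > 0) {
    pairs_needed <- spec$n_contradictions
    used <- character(0)
    while (length(planted_pairs) < pairs_needed) {
      uv <- sample(genes, 2L)
      key <- paste(uv, collapse = "|")
      if (key %in% used) next
      used <- c(used, key)
      s <- protein(uv[1]); o <- protein(uv[2])
      add_statement(s, "increases", o, object_activity = TRUE)
      add_statement(s, "decreases", o, object_activity = TRUE)
      note_causal(node_id(s), node_id(o), 1L)
      note_causal(node_id(s), node_id(o), -1L)
      planted_pairs[[length(planted_pairs) + 1L]] <-
        tibble(source = node_id(s), target = node_id(o))
    }
  }

  # planted all-negative correlation triangles (vertex-disjoint)
  planted_triangles <- list()
  if (spec$n_neg_triangles > 0) {
    avail <- setdiff(genes, unlist(lapply(planted_triangles, identity)))
    for (t in seq_len(spec$n_neg_triangles)) {
      trio <- sample(avail, 3L)
      avail <- setdiff(avail, trio)
      specs <- lapply(trio, protein)
      ids <- vapply(specs, node_id, character(1))
      add_statement(specs[[1]], "negativeCorrelation", specs[[2]])
      add_statement(specs[[2]], "negativeCorrelation", specs[[3]])
      add_statement(specs[[3]], "negativeCorrelation", specs[[1]])
      note_neg(ids[1], ids[2]); note_neg(ids[2], ids[3]); note_neg(ids[3], ids[1])
      planted_triangles[[length(planted_triangles) + 1L]] <-
        tibble(a = sort(ids)[1], b = sort(ids)[2], c = sort(ids)[3])
    }
  }

  # random statements, vetoing accidental motifs
  rels <- names(spec$relation_weights)
  w <- spec$relation_weights / sum(spec$relation_weights)
  made <- 0L
  guard <- 0L
  while (made < spec$n_statements && guard < spec$n_statements * 50L) {
    guard <- guard + 1L
    rel <- sample(rels, 1L, prob = w)
    s_name <- sample(genes, 1L)
    s_vars <- if (stats::runif(1) < spec$p_variant) "pmod(Ph)" else character(0)
    subject <- protein(s_name, variants = s_vars)
    sgn <- relation_sign(rel)
    if (sgn != 0L) {
      # causal: object is a gene product, a process, a pathology or a
      # foreign-species gene product
      kind <- sample(c("gene", "bp", "path", "foreign"), 1L,
                     prob = c(0.6, 0.2, 0.1, if (spec$n_foreign_genes > 0) 0.1 else 0))
      object <- switch(kind,
        gene = protein(sample(setdiff(genes, s_name), 1L)),
        bp = node_spec("bioprocess", "GOBP", sample(bps, 1L)),
        path = node_spec("pathology", "MESH", sample(paths, 1L)),
        foreign = if (stats::runif(1) < 0.5) protein(sample(mgi, 1L), ns = "MGI")
                  else protein(sample(rgd, 1L), ns = "RGD")
      )
      u <- node_id(protein(s_name)); v <- node_id(strip_variants(object))
      if (would_contradict(u, v, sgn)) next
      add_statement(subject, rel, object)
      note_causal(u, v, sgn)
    } else if (rel == "negativeCorrelation") {
      uv <- sample(genes, 2L)
      u <- node_id(protein(uv[1])); v <- node_id(protein(uv[2]))
      if (would_close_triangle(u, v)) next
      add_statement(protein(uv[1]), rel, protein(uv[2]))
      note_neg(u, v)
    } else {
      uv <- sample(genes, 2L)
      add_statement(protein(uv[1]), rel, protein(uv[2]))
    }
    made <- made + 1L
  }

  text <- render_corpus(spec, statements,
                        namespaces = list(
                          HGNC = genes, GOBP = bps, MESH = paths,
                          MGI = mgi, RGD = rgd
                        ))

  node_ids <- unique(unlist(lapply(statements, function(st) {
    c(node_id(st$subject), node_id(st$object))
  })))
  ledger <- list(
    n_statements = length(statements),
    node_ids = sort(node_ids),
    n_nodes = length(node_ids),
    contradictory_pairs = if (length(planted_pairs)) bind_rows(planted_pairs) else
      tibble(source = character(), target = character()),
    neg_triangles = if (length(planted_triangles)) bind_rows(planted_triangles) else
      tibble(a = character(), b = character(), c = character()),
    statement_table = tibble(
      subject = vapply(statements, function(st) node_id(st$subject), character(1)),
      relation = vapply(statements, function(st) st$relation, character(1)),
      object = vapply(statements, function(st) node_id(st$object), character(1)),
      pmid = vapply(statements, function(st) st$citation$pmid, character(1)),
      authors = lapply(statements, function(st) st$citation$authors[[1]]),
      annotations = lapply(statements, function(st) st$annotations)
    )
  )
  list(text = text, ledger = ledger)
}

strip_variants <- function(spec) {
  node_spec(spec$func, spec$namespace, spec$name)
}

render_corpus <- function(spec, statements, namespaces) {
  out <- c(
    'SET DOCUMENT Name = "Synthetic corpus"',
    paste0('SET DOCUMENT Version = "', spec$seed, '"')
  )
  for (kw in names(namespaces)) {
    terms <- namespaces[[kw]]
    if (length(terms) == 0) next
    out <- c(out, paste0("DEFINE NAMESPACE ", kw, " AS LIST {",
                         paste(bel_quote(terms), collapse = ", "), "}"))
  }
  for (kw in names(spec$annotations)) {
    out <- c(out, paste0("DEFINE ANNOTATION ", kw, " AS LIST {",
                         paste(bel_quote(spec$annotations[[kw]]), collapse = ", "), "}"))
  }
  for (st in statements) {
    cit <- st$citation
    fields <- c("PubMed", cit$name, cit$pmid, "",
                paste(cit$authors[[1]], collapse = "|"))
    out <- c(out, "",
             paste0("SET Citation = {", paste(bel_quote(fields), collapse = ", "), "}"),
             paste0("SET Evidence = ", bel_quote(st$evidence)))
    for (key in sort(names(st$annotations))) {
      out <- c(out, paste0("SET ", key, " = ", bel_quote(st$annotations[[key]])))
    }
    out <- c(out, paste(term_to_string(st$subject, st$subject_activity),
                        st$relation,
                        term_to_string(st$object, st$object_activity)),
             "UNSET ALL")
  }
  paste(out, collapse = "\n")
}

#' Generate a protein family/complex membership resource
#'
#' Builds a network consisting only of `hasMember` edges from each
#' family node to its member proteins, for use with [enrich_members()].
#'
#' @param families Named list mapping family name to a character vector
#'   of member protein names.
#' @param namespace Namespace keyword for all nodes.
#' @return A `knowledge_network`.
#' @export
generate_family_resource <- function(families, namespace = "HGNC") {
  if (length(families) == 0) return(knowledge_network())
  nodes <- list()
  edges <- list()
  for (fam in names(families)) {
    fspec <- node_spec("complex", namespace, fam)
    nodes[[length(nodes) + 1L]] <- node_spec_row(fspec)
    for (member in families[[fam]]) {
      mspec <- node_spec("protein", namespace, member)
      nodes[[length(nodes) + 1L]] <- node_spec_row(mspec)
      edges[[length(edges) + 1L]] <-
        synthetic_edge(node_id(fspec), node_id(mspec), "hasMember")
    }
  }
  knowledge_network(
    distinct(bind_rows(nodes), .data$id, .keep_all = TRUE),
    bind_rows(edges),
    name = "family resource"
  )
}

#' Default trajectory archetypes
#'
#' Stage-mean vectors (log2-fold-change scale) over the three disease
#' stages early/moderate/severe: `rise` increases throughout
#' progression, `late_fall` drops only at severe onset, `flat` is
#' unchanged, `elevated` is consistently high.
#'
#' @return Named list of numeric stage-mean vectors.
#' @export
default_archetypes <- function() {
  list(
    rise = c(early = 0.5, moderate = 1.5, severe = 3.0),
    late_fall = c(early = 0.5, moderate = 0.5, severe = -2.5),
    flat = c(early = 0.0, moderate = 0.0, severe = 0.0),
    elevated = c(early = 2.5, moderate = 2.5, severe = 2.5)
  )
}

#' Generate staged differential-expression tables
#'
#' Emulates a multi-stage disease progression design: each gene is
#' assigned a trajectory archetype, and its score at each stage is the
#' archetype's stage mean plus Gaussian noise. One omics table per stage
#' is returned, with the ground-truth archetype assignment.
#'
#' @param genes Tibble with columns `namespace`, `name`, and optionally
#'   `archetype` (archetype name per gene); without it archetypes are
#'   assigned round-robin.
#' @param stages Ordered stage labels.
#' @param archetypes Named list of stage-mean vectors (values aligned
#'   with `stages` by position).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed fixing the noise draws.
#' @return List with `tables` (named list of per-stage omics tibbles)
#'   and `truth` (tibble `namespace`, `name`, `archetype`).
#' @export
generate_staged_omics <- function(genes, stages = c("early", "moderate", "severe"),
                                  archetypes = default_archetypes(),
                                  noise_sd = 0.25, seed = 1L) {
  stopifnot(length(stages) >= 1, noise_sd >= 0,
            all(c("namespace", "name") %in% names(genes)))
  if (!"archetype" %in% names(genes)) {
    genes$archetype <- names(archetypes)[(seq_len(nrow(genes)) - 1L) %% length(archetypes) + 1L]
  }
  stopifnot(all(genes$archetype %in% names(archetypes)))
  withr::with_seed(seed, {
    tables <- lapply(seq_along(stages), function(si) {
      means <- vapply(genes$archetype, function(a) archetypes[[a]][[si]], numeric(1))
      tab <- tibble(
        namespace = genes$namespace, name = genes$name,
        score = unname(means) + stats::rnorm(nrow(genes), sd = noise_sd)
      )
      attr(tab, "experiment") <- stages[si]
      tab
    })
    names(tables) <- stages
    list(tables = tables, truth = genes[c("namespace", "name", "archetype")])
  })
}
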