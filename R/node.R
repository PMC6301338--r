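# Node specifications and canonical identifiers.
#
# A node is a typed biological entity: a function class (gene, rna, mirna,
# protein, abundance, complex, composite, bioprocess, pathology), a
# namespace keyword, a name, and an ordered list of variant descriptors
# (pmod()/var() strings). Identity is the canonical tuple
# (function, namespace, name, variants), rendered as a BEL-style term
# string which doubles as the vertex key throughout the package.

NODE_FUNCTIONS <- c(
  gene = "g", rna = "r", mirna = "m", protein = "p", abundance = "a",
  complex = "complex", composite = "composite",
  bioprocess = "bp", pathology = "path"
)

# long-form aliases accepted by the parser
FUNCTION_ALIASES <- c(
  g = "gene", geneAbundance = "gene",
  r = "rna", rnaAbundance = "rna",
  m = "mirna", microRNAAbundance = "mirna",
  p = "protein", proteinAbundance = "protein",
  a = "abundance", abundance = "abundance",
  complex = "complex", complexAbundance = "complex",
  composite = "composite", compositeAbundance = "composite",
  bp = "bioprocess", biologicalProcess = "bioprocess",
  path = "pathology", pathology = "pathology"
)

VARIANT_FUNCTIONS <- c("gene", "rna", "mirna", "protein")

#' Construct a node specification
#'
#' @param func Function class, one of `r paste(names(NODE_FUNCTIONS), collapse = ", ")`.
#' @param namespace Namespace keyword (e.g. `"HGNC"`).
#' @param name Entity name within the namespace.
#' @param variants Character vector of variant descriptors such as
#'   `"pmod(Ph)"`; only meaningful on gene/rna/mirna/protein nodes.
#' @return A list of class `node_spec`.
#' @export
#' @examples
#' node_spec("protein", "HGNC", "RB1")
node_spec <- function(func, namespace, name, variants = character()) {
  if (!func %in% names(NODE_FUNCTIONS)) {
    stop("unknown node function: ", func, call. = FALSE)
  }
  if (length(variants) > 0 && !func %in% VARIANT_FUNCTIONS) {
    stop("variants are only allowed on gene/rna/mirna/protein nodes", call. = FALSE)
  }
  structure(
    list(func = func, namespace = namespace, name = name,
         variants = as.character(variants)),
    class = "node_spec"
  )
}

quote_bel_name <- function(name) {
  if (grepl("[^A-Za-z0-9_]", name) || name == "") {
    paste0('"', gsub('"', '\\\\"', name), '"')
  } else {
    name
  }
}

#' Canonical identifier of a node
#'
#' Renders the identity tuple (function, namespace, name, variants) as a
#' BEL-style term string, e.g. `p(HGNC:RB1, pmod(Ph))`. Equal tuples give
#' equal strings, so the id serves as the vertex key.
#'
#' @param spec A `node_spec`.
#' @return A character scalar.
#' @export
node_id <- function(spec) {
  base <- paste0(spec$namespace, ":", quote_bel_name(spec$name))
  inner <- if (length(spec$variants) > 0) {
    paste(c(base, spec$variants), collapse = ", ")
  } else {
    base
  }
  paste0(NODE_FUNCTIONS[[spec$func]], "(", inner, ")")
}

# BEL term string including an optional activity qualifier wrapper
term_to_string <- function(spec, activity = FALSE) {
  s <- node_id(spec)
  if (isTRUE(activity)) paste0("act(", s, ")") else s
}

node_spec_row <- function(spec) {
  tibble(
    id = node_id(spec),
    func = spec$func,
    namespace = spec$namespace,
    name = spec$name,
    variants = list(spec$variants)
  )
}
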