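---
title: "Methods: compiling, querying and analyzing BEL knowledge networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compiling, querying and analyzing BEL knowledge networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belkit)
```

belkit implements a desk-scale environment for knowledge networks
encoded in the Biological Expression Language (BEL): compilation of BEL
scripts into directed multigraphs, statistical and motif summaries,
replayable subnetwork queries, and data-driven scoring of biological
processes by sign-aware heat diffusion. This vignette documents the
model underlying each component, the parameters that matter, the
numerical conventions, and the design choices made where the design was
genuinely open.

## The network model

A **node** is a typed biological entity: a function class (gene, RNA,
miRNA, protein, abundance, complex, composite, biological process,
pathology), a namespace keyword qualifying the vocabulary (e.g. HGNC
gene symbols), a name, and an ordered list of variant descriptors such
as `pmod(Ph)`. Node identity is exactly this tuple, rendered as a
canonical BEL-style term string (`p(HGNC:RB1, pmod(Ph))`) that also
serves as the vertex key. Variant order is identity-relevant; annotation
order never is.

An **edge** is one relational statement: subject, relation, object,
plus its citation, evidence sentence and annotation map. Edges carry a
derived **sign** (+1 for increases/directlyIncreases, −1 for
decreases/directlyDecreases, 0 otherwise) and a **symmetric** flag for
association and the two correlations. Symmetric relations are stored
once, not as two directed arcs, and every graph traversal treats them
bidirectionally; storing them once avoids double counting in statistics
and motif detection. Parallel edges between the same node pair are
allowed and meaningful — they are distinct curated assertions.

Activity qualifiers (`act(...)`) are recorded as edge-side flags on the
underlying entity node rather than as distinct nodes. This keeps the
two assertions "RB1 increases the transcriptional activity of E2F4" and
"RB1 decreases the transcriptional activity of E2F4" on a single node
pair, where the contradiction between them is detectable.

Merging networks takes the union of nodes by identity and concatenates
edge multisets, deduplicating only *exact* duplicates (same endpoints,
relation, full citation, evidence and annotations). Near-duplicates
that differ in provenance survive, preserving the multigraph semantics
of curated corpora. Merge is associative and commutative up to edge
order, and `merge(N, N) = N`.

## Parsing and validation

The parser accepts the BEL 1.0-style surface syntax: `SET DOCUMENT`
metadata, `DEFINE NAMESPACE`/`DEFINE ANNOTATION` headers, a
`SET`/`UNSET` context stack (citation, evidence, annotations) and
statement lines with short- or long-form relations. It is **total**: any
byte string yields a document in which every line is either consumed or
produces at least one issue with severity (error/warning), category
(syntactic/semantic), a stable code, and the verbatim line with 1-based
line and column (editor convention for curator feedback). Statements
inherit the currently-SET context; a relational statement without a
citation in scope is rejected with `MISSING_CITATION`.

Deliberately bounded grammar: names with spaces must be quoted; one
modifier level (`act()`) is allowed and deeper nesting is rejected;
`complex()`/`composite()` take a single namespaced name (the identity
tuple has no member slot — membership belongs in `hasMember` edges and
the enrichment resource). Namespaces defined `AS URL` are resolved only
through a caller-supplied resource map or a local file path; otherwise
the namespace stays unresolved, one warning is emitted per `DEFINE`
line (per-occurrence warnings would flood curator reports), and its
names pass unvalidated. The serializer emits resolved namespaces as
inline `DEFINE ... AS LIST {...}` definitions — a dialect extension the
parser also accepts — so parse∘serialize∘parse is a fixed point on the
statement multiset without any network access.

Recurring issues are grouped by (code, offending token), sorted by
count descending with ties broken by first line number, so a curator
sees the most impactful fix first.

## Summary statistics and biogrammar motifs

Density treats the multigraph as a simple directed graph of connected
ordered pairs: the number of distinct ordered pairs joined by at least
one edge (symmetric edges count both orders) divided by `n(n−1)`. This
keeps density in [0, 1] on multigraphs; whether parallel edges should
count is genuinely open, and the bounded convention was chosen. Average
degree is `2|E|/n` on the multigraph. Node overlap between two networks
is the Szymkiewicz–Simpson coefficient `|A∩B| / min(|A|,|B|)` over node
identities — 1 whenever one set contains the other, 0 if either is
empty.

Two motifs are built in, each a small curation-consistency signal:

- **Contradictory pair**: an ordered pair (u, v) carrying at least one
  +1 and one −1 causal edge. Direct and indirect forms are pooled by
  sign and activity qualifiers are ignored when pairing.
- **Inconsistent negative-correlation triple**: an unordered triple
  whose three pairs each carry a `negativeCorrelation` edge; as a
  correlation cycle the three signs cannot be simultaneously satisfied.
  Mixed-sign triangles (exactly one negative) are arguably also
  inconsistent but are not flagged; only the all-negative form is
  claimed.

`find_motifs()` accepts user-registered predicates for extension. Both
built-in finders are validated against brute-force enumeration
(O(E²)/O(n³)) and against planted ground truth on generated corpora.

## Queries: seeding and transformations

A query is a transaction: an ordered network selection, a list of seed
specifications, and a transformation pipeline. Running it merges the
selection, applies each seed to the assembly, unions the results
(multiple seeds combine by union; intersection semantics were the
alternative, but union matches the "one or several seeding methods"
use), then applies the pipeline left to right. Queries are pure —
rerunning on the same catalog gives byte-identical node-link JSON — and
hash to a SHA-256 of their canonical (key-sorted) JSON, so equal
queries get equal identifiers regardless of annotation-map order. Undo
removes the last pipeline step, then the last seed.

Directionality conventions, chosen explicitly:

- **Nth neighbors** ignores edge direction entirely (the visual
  neighborhood of a node), inducing all edges among nodes within
  undirected distance N.
- **Upstream/downstream** follow causal edges only, two layers deep,
  and induce only causal edges among the result.
- **Shortest paths / all paths** respect direction, with symmetric
  edges traversable both ways; all simple paths are bounded at six
  edges by default. All edges among the collected nodes are induced.
- **Provenance/authors/annotations** filter edges (authors match
  case-insensitively on the full name; annotation filters are OR
  within a key, AND across keys) and keep only the matching edges plus
  endpoints.

Transformations are registered by name in an extensible registry and
must be pure. The collapse operations are quotient maps: variant nodes
merge into their variant-free base; protein/RNA/miRNA nodes map to the
gene of the same namespace and name, with central-dogma edges inside a
collapsed group removed and duplicate edges deduplicated. Origin
enrichment inserts the RNA above each protein and the gene above each
RNA/miRNA, reusing existing nodes, so it is idempotent; membership
enrichment fires one hop only, for subjects already present in the
network. After origins → collapse variants → collapse to genes, no
protein/RNA/miRNA nodes remain, which is the intended input form for
omics overlay.

## Sign-aware heat diffusion

The diffusion operates on the causal subgraph. Parallel causal edges
between an ordered pair are first collapsed to their net sign
σ ∈ {−1, 0, +1}; pairs whose assertions cancel (σ = 0) are dropped and
reported — a contradictory pair carries no usable net polarity. Each
synchronous iteration, every non-sink node forwards its **entire**
working heat, split equally over its σ≠0 out-neighbors and multiplied
by σ, so crossing a decreasing edge flips the sign. Nodes without
outgoing causal edges are absorbing sinks (their initial heat counts as
absorbed). Iteration stops when the total working |heat| falls below
`tolerance` (default 1e−8) or at `max_iterations` (default 100, which
guarantees termination on cycles; on a DAG the process converges
exactly after the longest-path length). The reported final heat is the
absorbed heat on sinks and the residual working heat elsewhere.

These update rules make the process linear in the initial heats, exactly
equal to the path-sum Σ over paths of h₀ · Π(σ/outdeg) on DAGs, and
conservative when all signs are positive — the three properties the
test suite verifies against an independent path-enumeration oracle.
Alternative conventions (damped updates, degree-normalized kernels as
in HotNet-style propagation) would also be defensible; the
full-forwarding absorbing form was fixed because it is deterministic,
oracle-checkable, and preserves the qualitative rules of the workflow
(iterative spread, sign flip on decreases, readout at biological
processes).

Omics scores default to signed log2 fold changes; significance
filtering is deliberately the caller's job, since tables are expected
to be pre-processed. Mapping is exact on (namespace, name) with
case-insensitive keywords and case-sensitive names, and reports both
unmatched rows and unmapped gene nodes.

## Trajectory clustering

Per-experiment biological-process heats form trajectory vectors
(missing entries 0; nodes sorted internally so input order never
matters). These are partitioned with `stats::kmeans` — Euclidean
distance, 10 random restarts, best inertia kept, all under a fixed
seed, so results are deterministic. The established Hartigan–Wong
implementation was preferred over a hand-rolled farthest-point
initialization: the workflow fixes only K (5 in the staged analysis)
and determinism, both of which the seeded restarts provide. If fewer
distinct trajectories than K exist, each distinct trajectory becomes
its own cluster without error. Heats are clustered raw by default;
`standardize = TRUE` opts into per-experiment unit-variance scaling,
since whether normalization precedes clustering is not fixed by the
workflow definition.

Cluster/archetype agreement is measured by mapping each cluster to its
modal planted label and scoring the fraction of matches; the measure is
1 whenever the clustering refines the planted partition (e.g. K = 5 on
four well-separated archetypes).

## The synthetic-data generators

`generate_corpus()` emits a valid BEL script plus a ground-truth
ledger. Motifs are planted by *count* (the ledger must be exact, so
counts replace sampling probabilities), and random statements that
would accidentally complete a contradictory pair or an all-negative
triangle are rejected and resampled. Defaults — 60 statements over 25
genes, 5 processes, 2 pathologies, 8 citations, 2 planted
contradictions, 1 planted triangle, causal-heavy relation mixture —
describe a small curated corpus at desk scale. The staged scenario
generator builds 4 curated-mechanism subgraphs × 5 biological processes,
each process driven by 3 dedicated genes, plus the material the
pre-processing pipeline must strip (mouse/rat namespaces, pathology
hubs, correlative edges, protein variants, a protein family).

`generate_staged_omics()` draws per-gene scores from four trajectory
archetypes over the stages early/moderate/severe — rising (0.5, 1.5,
3.0), late-falling (0.5, 0.5, −2.5), flat (0, 0, 0), elevated (2.5,
2.5, 2.5), on the log2-fold-change scale typical of moderate
differential expression — plus Gaussian noise (sd 0.25 by default,
small relative to the effects so planted structure is recoverable).

What the generators emulate: the grammar, context stack, provenance and
annotation structure of curated BEL; motif frequencies; a staged
differential-expression design with distinct progression patterns. What
they do not: real biological topology (hubs, modularity), curation
error patterns, correlated noise between stages, or the identifier
messiness of real namespaces. Passing tests therefore demonstrate
correctness of the algorithms under the stated semantics, not
robustness to the full heterogeneity of real corpora.

## Problem sizes and runtime

The test suite validates against independent oracles at deliberately
small scales where exhaustive enumeration is exact: fuzzing with 1 000
random inputs; 100 round-trip corpora; 200 random networks (≤ 40
nodes) for seed-method equivalence; 100 DAGs (≤ 15 nodes) for the
diffusion path-sum oracle at 1e−10; 20 end-to-end staged runs for
archetype recovery. The full suite runs in a few minutes on one CPU.

## Known limitations

- BEL 2.x constructs, nested complex members, fusion/location terms
  and network-fetched `.belns` resources are out of scope.
- Contradiction reporting does not weight assertions by biological
  context, reference type or publication date; all curated statements
  count equally.
- The diffusion's numerical agreement with any particular web-service
  implementation is not claimed — only the qualitative rules stated
  above, which the update scheme fixes precisely.
- `run_query()` holds catalogs in memory; there is no database
  persistence or access control.

```{r example}
res <- run_staged_analysis(seed = 1)
head(res$trajectories$trajectories)
res$agreement
```
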