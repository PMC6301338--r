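# belkit

Causal knowledge networks from the Biological Expression Language, in R.

BEL (Biological Expression Language) encodes qualitative causal and
correlative biological relations as subject–predicate–object triplets —
`p(HGNC:RB1) increases act(p(HGNC:E2F4))` — each qualified by a citation,
an evidence sentence and contextual annotations. Curated BEL corpora
assemble into directed multigraph knowledge networks spanning molecular,
pathway and phenotypic scales. belkit is for curators and systems
biologists who want to work with such corpora offline and scriptably:

- **Compile**: parse and validate BEL 1.0-style scripts with positional
  error reporting (syntactic/semantic issue codes, line and column),
  recurring-issue grouping, and round-trip serialization back to BEL.
- **Summarize**: node/edge/citation counts, density, average degree,
  betweenness, node overlap between networks by the Szymkiewicz–Simpson
  coefficient |A∩B| / min(|A|,|B|), and "biogrammar" motifs that flag
  curation inconsistencies — the *contradictory pair* (A increases B and
  A decreases B both curated) and the *inconsistent negative-correlation
  triple* (three nodes pairwise negatively correlated, impossible as a
  sign-consistent cycle).
- **Query**: replayable seed/transform transactions. Eight seed methods
  (Nth neighbors, two-layer upstream/downstream along causal edges,
  shortest paths, bounded all paths, citation provenance, authors,
  annotations) extract subnetworks from a merged assembly; a
  transformation registry (extract causal edges, remove pathology hubs,
  delete namespaces, enrich family members, enrich protein/RNA origins,
  collapse variants, collapse to genes, ...) post-processes them. Queries
  serialize to JSON, hash to stable SHA-256 identifiers, replay
  deterministically and unwind step by step.
- **Analyze**: overlay differential-expression scores as node heats and
  diffuse them over the causal subgraph. Each synchronous step a
  non-sink node forwards its heat, split equally over its causal
  out-neighbors; crossing a *decreases* edge flips the sign, so mixed
  polarity aggregates correctly. Sinks absorb heat; the readout is the
  final heat on biological-process nodes. Multi-experiment heat
  trajectories (e.g. early/moderate/severe disease stages) are clustered
  with K-means (K = 5 in the staged workflow) to reveal progression
  patterns.
- **Simulate**: deterministic generators of synthetic BEL corpora with
  ground-truth ledgers (planted motifs, citation/annotation
  assignments), family-membership resources, and staged omics tables
  with planted trajectory archetypes, so everything is testable with no
  network access.

## Worked example

```r
library(belkit)

bel <- paste(
  'SET DOCUMENT Name = "RB1 example"',
  'DEFINE NAMESPACE HGNC AS LIST {"RB1", "E2F4"}',
  'SET Citation = {"PubMed", "Li 1997", "9342358"}',
  'SET Evidence = "RB1 regulates the transcriptional activity of E2F4."',
  "p(HGNC:RB1) increases act(p(HGNC:E2F4))",
  "p(HGNC:RB1) decreases act(p(HGNC:E2F4))",
  sep = "\n")

net <- compile_network(parse_bel_document(bel))
glance(net)
#> # A tibble: 1 × 5
#>   nodes edges citations density average_degree
#>   <int> <int>     <int>   <dbl>          <dbl>
#> 1     2     2         1     0.5              2

find_contradictory_pairs(net)[, 1:4]
#> # A tibble: 1 × 4
#>   source      target       n_positive n_negative
#>   <chr>       <chr>             <int>      <int>
#> 1 p(HGNC:RB1) p(HGNC:E2F4)          1          1
```

The two statements assert opposite causal effects of RB1 on the
transcriptional activity of E2F4, so the network's single node pair is
reported as a contradictory pair (activity qualifiers are ignored when
pairing, by design).

The full staged-progression workflow — annotation seeding, the
pre-processing pipeline, three-stage omics overlay, diffusion and
K-means clustering — runs end to end on a synthetic corpus:

```r
res <- run_staged_analysis(seed = 1)
head(res$trajectories$trajectories, 4)
#> # A tibble: 4 × 5
#>   node                                early moderate  severe cluster
#>   <chr>                               <dbl>    <dbl>   <dbl>   <int>
#> 1 "bp(GOBP:\"synthetic process 1\")"  1.18     5.26   9.16         4
#> 2 "bp(GOBP:\"synthetic process 10\")" 1.12     1.58  -8.23         2
#> 3 "bp(GOBP:\"synthetic process 11\")" 0.411    0.456  0.0284       0
#> 4 "bp(GOBP:\"synthetic process 12\")" 7.04     8.21   6.63         1
res$agreement
#> [1] 1
```

Each row is a biological process with its diffused heat at the three
disease stages and its K-means cluster; `agreement` is the fraction of
processes whose cluster matches their planted trajectory archetype
(rising, late-falling, flat, elevated). `autoplot(res$trajectories)`
draws the parallel-coordinates view.

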