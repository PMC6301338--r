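Package: belkit
Title: Causal Knowledge Networks from the Biological Expression Language
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles Biological Expression Language (BEL) scripts into
    directed multigraph knowledge networks and supports their exploration
    and analysis: parse and validate BEL with positional error reporting,
    summarize networks statistically and via biogrammar motifs
    (contradictory pairs, inconsistent negative-correlation triples),
    extract subnetworks with replayable seed/transform query transactions,
    overlay omics scores and score biological processes by sign-aware heat
    diffusion, and cluster multi-experiment heat trajectories. Includes
    deterministic generators of synthetic BEL corpora and staged
    differential-expression tables for fully offline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
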