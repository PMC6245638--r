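Package: orthopath
Title: Step-Wise Reciprocal-Best-Hit Ortholog Chains Along Evolutionary Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Traces the evolutionary history of a query protein by repeated
    reciprocal-best-hit searches along an ordered path of proteomes, producing
    a chain of orthologs and homologs anchored at the taxon where the query
    enters the path.  A deterministic Smith-Waterman search backend with
    Karlin-Altschul statistics is built in; an adapter for external BLAST+
    tabular reports is provided.  Optional analyses project a locked region of
    the query through the chain's alignments (with fragment rescue and a
    position-frequency/information-content logo) and profile per-taxon
    presence ratios of GO terms over sets of query proteins.  A seeded
    synthetic-data generator emits evolutionary paths and protein families
    with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
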