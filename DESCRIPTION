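Package: hadalvirome
Title: Post-Assembly Viromics for Hadal Sediment Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based curation and ecology of viral contigs recovered from
    deep-sea sediment metagenome assemblies. Implements keyword/quorum viral
    triage with blank-control decontamination and genome quality tiers,
    species-level vOTU clustering at 95% average nucleotide identity over
    85% of the shorter contig, gene-sharing genus clustering with
    hypergeometric edge significance, majority-rules family taxonomy,
    four-evidence virus-host linkage (homology, CRISPR spacers, shared tRNAs,
    k-mer composition) with integrated confidence scoring, coverage-based
    community ecology (per-gigabase normalization, Chao1/ACE/Shannon/inverse
    Simpson, Bray-Curtis PCoA, PERMANOVA), auxiliary-metabolic-gene screening
    with positional viral-context checks, and a ground-truthed synthetic-data
    generator so the whole pipeline is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
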