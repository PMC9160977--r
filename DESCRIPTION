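Package: mutminer
Title: Mining and Sequence Validation of Mutation Mentions in Scientific Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid literature-mining pipeline for protein-coding variant
    curation. Extracts mutation mentions from plain-text scientific papers with
    an ordered regular-expression block and a gated rule-based natural-language
    block, normalizes mentions to canonical one-letter substitution form (e.g.
    V600E), links genes, strains, alleles and experimental metadata through
    user-supplied dictionaries, validates every candidate gene-mutation pair
    against a proteome by checking the claimed reference residue (or a
    degenerate codon encoding it) in at least one isoform, and emits
    curator-ready structured output together with precision/recall/F1 metrics
    against gold annotations. Ships a deterministic synthetic-corpus generator
    with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
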