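Package: igome
Title: Serum Antibody Epitope Repertoire Analysis from Display-Library Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of serum antibody epitope repertoires ("IgOmes") captured
    by random-peptide display libraries and deep sequencing. Extracts and
    translates 36-bp variance-region inserts, removes sequencing noise with a
    10-sigma-99 read-count floor, partitions distinct epitopes between case and
    control pools into unique and fold-enriched common sets, annotates epitopes
    against a reference proteome by exact short-peptide matching with a
    unit-interval significance score, profiles microbial taxa by
    reads-per-epitope normalised abundance (NGSR e-norm), triages human
    autoantibody targets with overlap and gene-set coverage statistics, and
    detects candidate molecular-mimicry events between human and microbial
    epitopes with Kimura protein distances and neighbour-joining phylogenies.
    Includes a fully seeded synthetic display-library generator with planted
    ground truth so every stage is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
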