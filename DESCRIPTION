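Package: mgrquant
Title: Quantification of Mitochondrial Genome Rearrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies rearrangement of circular mitochondrial gene orders
    against a reference arrangement. Computes per-gene rearrangement scores
    (RS, the number of changed flanking neighbours, 0-2), per-genome RS, and
    per-gene rearrangement frequencies (RF) within taxonomic groups;
    canonicalizes circular arrangements and takes a census of global and
    local arrangement patterns (major vs rare); tests phylogenetic clustering
    of rearranged genomes by hypergeometric clade enrichment and bounds
    pattern occurrence times by dated most-recent-common-ancestor nodes; and
    simulates gene-order evolution on a phylogeny under tandem duplication,
    tandem duplication-random loss, transposition, inversion and gene loss,
    with hotspot placement and ground-truth event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
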