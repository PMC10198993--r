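Package: mirfish
Title: Network-Based Prioritization of Compound Targets and Regulatory microRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for prioritizing the protein targets of
    a bioactive compound and the microRNAs that regulate them. Implements
    ligand-based target fishing with substring-hash fingerprints and Tanimoto
    similarity, construction and sphere expansion of protein-protein
    interaction networks from STRING-format edge lists, scale-free (power-law)
    degree-distribution fitting for network selection, Maximal Clique
    Centrality (MCC) hub ranking via Bron-Kerbosch clique enumeration,
    four-tool miRNA target-prediction consensus with per-tool score
    thresholds, single-strandedness accessibility filtering of 3'UTR binding
    sites, a simplified nearest-neighbor RNA duplex free-energy model, and
    rank-sum candidate selection. Includes a synthetic-data module that
    generates scale-free and random interactomes, prediction tables with
    planted consensus targets, and accessibility profiles with planted
    accessible windows, so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
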