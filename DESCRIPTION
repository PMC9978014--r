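Package: commassembly
Title: Community Assembly Processes, Niche Breadth and Co-Occurrence
    Networks for Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the ecological processes structuring microbial
    communities from an OTU count table, a rooted phylogeny and an
    environmental table.  Partitions taxa into abundant and rare classes,
    computes alpha diversity and Bray-Curtis ordination, estimates Levins'
    niche breadth with a count-preserving permutation null to classify
    generalists and specialists, attributes community assembly to
    selection, dispersal and drift via beta-nearest-taxon-index (betaNTI)
    and Raup-Crick (Bray-Curtis) null models, builds thresholded Spearman
    co-occurrence networks with topology summaries, and relates
    phylogenetic turnover to environmental gradients with Mantel tests.
    Includes a synthetic-community generator with known assembly regimes
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
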