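Package: microassembly
Title: Assembly Processes and Co-Occurrence Networks for Rare and
    Abundant Microbial Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the ecological processes structuring microbial
    communities from an OTU table and a rooted phylogeny. Implements the
    seven-category rare/abundant taxon classification (always/conditionally
    rare and abundant taxa), phylogenetic null-model partitioning of
    community assembly into variable selection, homogeneous selection,
    dispersal limitation, homogenizing dispersal and undominated processes
    via the beta nearest taxon index (betaNTI) and the Bray-Curtis-based
    Raup-Crick metric (RC-Bray), and thresholded Spearman co-occurrence
    networks with node- and network-level topology, natural-connectivity
    robustness curves, Louvain modularity and seasonal enrichment census.
    A synthetic metacommunity simulator with known selection and dispersal
    regimes (Yule phylogeny, Brownian-motion niche evolution, Gaussian
    environmental filtering) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
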