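Package: cervsym
Title: Phylosymbiosis Analysis of Host-Associated Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing phylosymbiosis, the congruence between a host
    phylogeny and the compositional relationships of host-associated microbial
    communities. Provides OTU-table input/output with rarefaction and
    singleton filtering, alpha-diversity indices (observed OTUs, bias-corrected
    Chao1, Shannon, Simpson, equitability, Good's coverage), core and shared
    OTU accounting, Jaccard and UniFrac dissimilarities with principal
    coordinates analysis, UPGMA dendrograms, rooted Robinson-Foulds and
    Matching Cluster tree distances with exact and Monte-Carlo
    randomized-topology null distributions, Mantel and ANOSIM permutation
    tests, and a synthetic host-microbiome codivergence generator for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn,
    optparse
Config/testthat/edition: 3
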