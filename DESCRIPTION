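Package: paradecay
Title: Distance Decay of Parasite Community Similarity Across Host
    Phylogeny and Geography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the structure of metazoan parasite
    communities across multiple host species sampled at multiple sites,
    built around the distance-decay framework: community descriptors
    (prevalence, mean abundance, infracommunity richness), Jaccard and
    Bray-Curtis similarity matrices, uncorrected p-distances from aligned
    marker sequences, great-circle geographic distances, permutation-based
    multiple regressions of log-similarity on phylogenetic and geographic
    distance, PERMANOVA and PERMDISP tests with pairwise Bonferroni
    comparisons, principal-coordinates ordination, average-linkage
    clustering, Poisson and negative-binomial richness models, and species
    accumulation curves. A synthetic host-parasite assemblage generator
    with known decay structure supports end-to-end testing and parameter
    recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    jsonlite,
    phangorn,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
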