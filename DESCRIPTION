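Package: cpamotif
Title: Specificity-Determining Motif Discovery and Classification for
    Cation/Proton Antiporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolutionary analysis of the cation/proton antiporter
    (CPA) superfamily: simulation of clade-structured protein families with
    planted motif states, sequence pre-processing filters (length screen,
    greedy identity clustering, essential-region coverage), profile hidden
    Markov model construction and glocal Viterbi alignment, desk-scale
    phylogenetics (maximum-likelihood pairwise distances, neighbor joining,
    bootstrap bipartition supports, greedy phylogenetic-diversity subset
    selection), tree-aware per-site conservation scoring with discrete-gamma
    rate variation, mutual-information discovery of specificity-determining
    columns, residue-rule classification of CPA1/CPA2 membership,
    electrogenicity and Na+/K+ ion selectivity, and mapping of motif
    positions onto protein structures with salt-bridge detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
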