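Package: amazontraits
Title: Phylogenetic Signal and Macroecology of Genus-Level Characteristics
    in Amazonian Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis pipeline for genus-level characteristics
    of Amazonian trees (species richness, mean range size, mean abundance)
    on a time-calibrated genus phylogeny. Implements Brownian-motion
    likelihood and Pagel's lambda maximum-likelihood estimation with AIC
    model comparison, Felsenstein's phylogenetically independent contrasts
    with raw and through-origin correlation tests, maximum-likelihood
    ancestral state reconstruction with a tip-randomization significance
    scan for lineages with unusually high or low values, and one-way
    ANOVA with Tukey HSD comparisons across major angiosperm clades.
    Includes a synthetic-data module (birth-death trees, correlated traits
    evolving with tunable phylogenetic signal) so the full pipeline is
    testable end to end without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
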