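Package: hadromosaic
Title: Model-Based Discretization of Osteological Measurements and
    Maximum-Parsimony Analysis for Hadrosauroid Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative taxonomic placement of transitional
    hadrosauroid dinosaurs.  One track fits univariate Gaussian mixture
    models by expectation-maximization with BIC model selection to
    partition continuous osteological measurement attributes (ratios,
    angles) into discrete value intervals, maps the intervals onto the
    basal-hadrosauroid versus hadrosaurid split, derives boundary values
    between adjacent intervals, and classifies a focal taxon attribute by
    attribute to detect mosaic (straddling) placements.  The other track
    is an equally-weighted maximum-parsimony engine for morphological
    character-taxon matrices with missing and polymorphic cells: Fitch
    scoring, per-character minimum and maximum steps, ensemble
    consistency and retention indices, random-addition Wagner tree
    construction, TBR branch swapping, strict and majority-rule
    consensus, bootstrap proportions, Bremer decay indices, and
    unambiguous-synapomorphy mapping.  Includes seeded generators for
    two-group Gaussian measurement data and discrete characters evolved
    on known trees with fossil-like missingness, readers and writers for
    NEXUS/TNT matrices and Newick trees, and an end-to-end pipeline
    interface with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    phangorn,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
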