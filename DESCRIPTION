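Package: wgdplacer
Title: Placing Whole Genome Duplications on Species Phylogenies from
    Gene Families and Synonymous Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infrastructure for detecting and phylogenetically placing
    whole genome duplications (WGDs) from coding-sequence data. Computes
    paralog and ortholog Ks (synonymous substitutions per synonymous
    site) distributions with NG86 counting, fits normal mixture models
    with AIC selection and scans for significant slope changes in the Ks
    density (a SiZer-style analysis), rate-corrects ortholog divergence
    with focal/sister/outgroup trios, maps duplications from rooted gene
    trees onto a ladderized species tree by LCA reconciliation, estimates
    gene birth and death rates by a linear birth-death pruning
    likelihood, contrasts empirical duplication profiles against
    simulated null and positive gene-tree distributions with Fisher's
    exact tests, and quantifies duplicate retention and GO Slim
    functional bias of retained paralogs. A synthetic-data module
    simulates birth-death gene families with planted WGDs, codon
    sequences with controlled synonymous divergence, and GO tables with
    planted category bias, so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
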