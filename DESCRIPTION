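Package: normlap
Title: Normalized Network Overlap with Maximum-Entropy Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the agreement between two undirected networks that share
    a node namespace. The raw edge overlap between two interactome maps is hard
    to interpret because node degrees disagree between maps; this package brackets
    the observed overlap between a degree-preserving maximum-entropy null model
    (negative benchmark, randomization over the complete graph) and a best-case
    ensemble that resamples the reference network from the union of the two
    networks (positive benchmark). The observed overlap rescaled between the two
    benchmark means is the Normlap score. Includes analytic overlap moments
    without sampling, one-sided significance tests and a compatibility
    classification, thresholding and computational validation of score-ranked
    candidate networks, all-pairs agreement networks, seedable synthetic fixtures
    with independent Monte-Carlo and root-finding oracles, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    optparse,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
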