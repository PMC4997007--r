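Package: triplimit
Title: Multilocus Species Delimitation from Rooted Triplet Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rapid multilocus species delimitation under the multispecies
    coalescent using the distribution of rooted triplet topologies across
    gene trees. Triplet counts for three samples follow a uniform trinomial
    distribution when the samples belong to one panmictic species and a
    skewed trinomial distribution when they span species boundaries; a
    Bayesian model comparison with analytic (incomplete-beta) marginal
    likelihoods yields per-triplet posterior probabilities, and an exact
    dynamic program over a guide tree finds the delimitation with the
    highest additive posterior score. Includes a multispecies-coalescent
    gene-tree simulator, a majority-triplet guide-tree builder, scripted
    simulation studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    Rcpp,
    stats,
    utils,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
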