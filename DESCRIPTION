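Package: popconcord
Title: Concordance of Demographic Models with Population-Genetic Summaries
Version: 0.1.0
Authors@R:
    person("popconcord", "developers", email = "popconcord@example.org",
           role = c("aut", "cre"))
Description: Tools to encode published piecewise demographic histories
    (stepwise single-population trajectories from whole-genome coalescent-HMM
    output, multi-population models with migration and pulse admixture),
    predict the summaries of genetic variation they imply -- the expected
    site frequency spectrum (analytic time-inhomogeneous coalescent or Monte
    Carlo), windowed expected heterozygosity, and linkage-disequilibrium
    decay -- and rank models against an observed spectrum by multinomial and
    Poisson log-likelihoods.  Includes a built-in coalescent simulator
    (unlinked genealogies and recombining sequence blocks under the SMC'
    approximation) so that every analysis can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
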