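Package: darkaffinity
Title: Dark Diversity Affinity Models for Species-Site Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates dark diversity affinity (DDA) - the joint tendency of a
    species to be absent from ecologically suitable sites and of a site to lack
    suitable species - from binary presence-absence metacommunity matrices,
    species traits and site attributes. Provides hypergeometric co-occurrence
    suitability estimation, a Bayesian species-site unified logistic model
    fitted by adaptive Markov chain Monte Carlo with Gelman-Rubin convergence
    gating, posterior classification of dark-diversity-affine species and
    sites, Kruskal-Wallis comparison of absent versus present species-site
    subsets, and a synthetic metacommunity generator with a parameter-recovery
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
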