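Package: msneutral
Title: Multi-Site Neutral Community Models via Hierarchical Dirichlet
    Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian fitting of Hubbell's multi-site neutral model of
    community assembly approximated by a hierarchical Dirichlet process.
    Provides a Gibbs sampler for the fundamental biodiversity number and
    per-site immigration rates from OTU count tables, Monte Carlo
    goodness-of-fit (pseudo-P) neutrality tests at the metacommunity and
    local-community level, synthetic-data generators (neutral and
    niche-structured metacommunities, a forward Moran simulator), and a
    pipeline for couple-level semen/vaginal microbiome transmission
    analyses across multiple metacommunity groupings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    vegan
Config/testthat/edition: 3
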