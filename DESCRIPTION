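Package: quantevol
Title: Iterated Learning of Quantifier Meanings with Neural Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the cultural evolution of generalized-quantifier
    meanings in chains of neural-network agents. Quantifiers are Boolean
    truth tables over fixed-size structures; each generation of small
    feedforward networks learns its cultural parent's quantifier through a
    limited data bottleneck, optionally through a bit-shuffling channel
    that destroys object identity. Graded information-theoretic measures
    quantify the degree of monotonicity and of quantity (permutation
    invariance) of the evolving quantifiers, together with combinatorial
    utilities, pattern classification of evolved meanings, random
    baselines, and a reproducible experiment-grid driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
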