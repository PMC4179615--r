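Package: branchcov
Title: Branch-Length Based Covariance of Pairwise Maximum-Likelihood
    Evolutionary Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of pairwise maximum-likelihood evolutionary
    distances under r-state symmetric and general Markov substitution
    models, together with a constant-time estimator of the covariance
    between two distance estimates whose leaf-to-leaf paths overlap on
    the underlying tree ("branch-covariance").  The covariance of two
    distances sharing a path of length delta_m is evaluated as the
    asymptotic variance of an ML distance estimate at true distance
    delta_m; the shared path length is recovered from the six pairwise
    distances of the quartet by weighted least squares.  Includes the
    linear-time sample-average (Susko) covariance baseline, a quartet
    sequence simulator with optional Zipfian indels and global pairwise
    re-alignment, and a Monte-Carlo harness that validates every
    estimator against replicate sample covariances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    Matrix,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
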