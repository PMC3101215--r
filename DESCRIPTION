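Package: adpart
Title: Adaptive Partition Detection of Multiple Change-Points
Version: 0.1.0
Authors@R: person("adpart", "developers", email = "adpart@example.org",
    role = c("aut", "cre"))
Description: Partitions an ordered "time course" (age, body-mass index,
    chromosomal position, ...) into consecutive blocks whose population
    means or proportions differ significantly at a user-chosen level alpha
    between every pair of adjacent blocks.  The globally optimal
    (maximum-likelihood, minimum-SSE) restricted partition is found by a
    modified dynamic programming algorithm with a feasibility screen;
    greedy recursive-combination and recursive-partition baselines, a
    permutation F-type test of "no change-point", bootstrap time-point-wise
    confidence intervals, cross-validated selection of alpha, a binary
    (0/1) response mode, and a simulation harness are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
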