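Package: proctol
Title: Tolerance-Limit Inference for Log-Normal Procedure Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical analysis of clinical procedure times against fixed
    tolerance limits. Fits and compares candidate time distributions
    (log-normal, normal, Weibull) with Shapiro-Wilk and Pearson chi-square
    goodness-of-fit tests, computes upper confidence limits on the
    probability that a procedure time exceeds a tolerance limit by
    generalized pivotal quantity Monte Carlo and by the exact noncentral-t
    construction, provides exact Clopper-Pearson binomial bounds for
    zero-event counts, rank-association tests (Kendall tau-b, Spearman rho)
    with Monte Carlo permutation p-values, a rolling experience-threshold
    scan for selecting analyzable subcohorts, and a seeded synthetic cohort
    generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), MASS, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
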