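Package: mimvar
Title: Comparing Treatment-Group Variances with a Control Variance
Version: 0.1.0
Authors@R: person("mimvar", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests whether any of k normal treatment groups has a smaller
    variance than a control group (the lower one-sided, tree-ordered
    alternative).  Implements a marginal inferential model (MIM) test based
    on the plausibility of theta = min(sigma_1^2, ..., sigma_k^2)/sigma_0^2,
    valid for unequal sample sizes, together with Spurrier's exact
    multivariate-F test for the equal-sample-size case.  The null
    distribution of the control-to-minimum variance ratio is computed by
    deterministic quadrature with a Monte-Carlo cross-check, plausibility
    curves are inverted into one-sided confidence bounds, and a simulation
    harness estimates type-I-error rates and power over replicated normal
    studies.  Long-format data ingestion, a Shapiro-Wilk normality screen,
    and a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
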