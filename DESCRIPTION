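Package: cagedom
Title: Dominance Hierarchy Analysis for Group-Housed Mice from Home-Cage
    Behavior
Version: 0.1.0
Authors@R:
    person("A.", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring and validating dominance hierarchies in
    group-housed laboratory mice from coded home-cage behavior. Reads
    all-occurrence social interaction events and instantaneous scan samples,
    builds directed frequency and binary sociomatrices with network summaries
    (density, directional consistency, in-/out-strength), computes Glicko-1
    dominance ratings from aggression and from submission contest streams,
    scores wound severity (pelt aggression lesion scale), tube-test dominance,
    preputial gland ratio, time budgets and solitary occupancy, and runs a
    convergent/discriminant validity workflow (standardization, mixed-model
    residualization, maximum-likelihood factor analysis with varimax rotation,
    factor-score regressions, Pearson correlations, and a submission-response
    logistic analysis with Bonferroni-corrected contrasts). A synthetic cage
    study generator with configurable despotism, strain effects, and
    observational sampling supports end-to-end testing without video-coded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
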