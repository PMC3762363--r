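Package: groupmaxent
Title: Maximum Entropy Models of Multi-Animal Group Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying correlated group behavior from discretized
    multi-animal zone-occupancy time series. Estimates the empirical joint
    distribution of group configurations, measures total group correlation
    (multi-information) and synergistic information about each animal, fits a
    hierarchy of Potts-style maximum entropy models constrained by marginals of
    increasing order (with generalized iterative scaling and gradient-ascent
    refinement), decomposes the multi-information into per-order interaction
    contributions, infers sparse functional interaction maps by L1-regularized
    model selection, and compares groups through permutation-minimized
    Jensen-Shannon divergence between their fitted models. Includes a synthetic
    occupancy-series generator with heterogeneous zone preferences, sparse
    predominantly negative couplings, and power-law-like dwell times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
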