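Package: firereserve
Title: Reserve Site Selection Under Spatially Correlated Disturbance Risk
Version: 0.1.0
Authors@R:
    person("firereserve", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for probabilistic maximal-covering reserve site selection
    when the disturbance threatening habitat (fire, pests, disease) spreads
    across space. Builds square-grid and hexagonal-lattice landscapes,
    enumerates or simulates spreading burn patterns and their risk-equalized
    spatially-independent counterparts, evaluates candidate reserves by the
    expected number of surviving species together with the full outcome
    distribution, and solves for optimal reserves by exhaustive enumeration on
    small landscapes or simulated annealing on large ones. Includes generators
    for synthetic species presence/absence matrices and a small command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
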