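Package: acmine
Title: Target Set-Dependent Activity Cliff Mining with Matched Molecular Pairs
Version: 0.1.0
Authors@R: person("ACMine", "Developers", email = "acmine.dev@example.org",
    role = c("aut", "cre"))
Description: Identifies activity cliffs in compound activity classes using
    matched molecular pairs (MMPs) generated by single-cut fragmentation,
    optionally restricted to retrosynthetic bond environments (RMMPs).
    Potency-difference thresholds are derived per target set from the
    distribution of pairwise potency differences (mean plus two standard
    deviations), cliffs involving confirmed inactive analogs are called via
    an activity-cliff-relevant potency criterion, and cliff compounds are
    organized into networks whose connected components expose coordinated
    cliffs. Includes a synthetic analog-series generator so the complete
    workflow is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
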