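Package: pdmilestones
Title: Milestone-Based Composite Progression Endpoints for Parkinson's Disease Cohorts
Version: 0.1.0
Authors@R: person("PPMI", "Methods", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for monitoring Parkinson's disease progression with a
    composite endpoint built from 25 clinically defined milestones spanning
    six domains (walking and balance, motor complications, cognition,
    autonomic dysfunction, functional dependence, activities of daily
    living). Provides a declarative milestone registry evaluated on
    item-level longitudinal assessments under a conservative missing-data
    rule; derivation of the time-to-first-milestone endpoint from annual or
    all scheduled visits; Kaplan-Meier estimation on per-protocol time and a
    screening/backward-selection Cox workflow with a time-dependent
    medication covariate; stability (reverter) analyses of milestone
    persistence; log-rank sample-size calculation against a piecewise-linear
    control survival curve (Schoenfeld and Lakatos methods) with a power
    simulator; and a synthetic longitudinal cohort generator with exact
    ground truth for end-to-end validation without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
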