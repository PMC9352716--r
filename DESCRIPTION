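Package: navdis
Title: Scoring and Group Analysis of Virtual-Reality and Real-World Spatial-Navigation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores three spatial-navigation assessments used in dementia
    research - a 14-trial virtual supermarket test (egocentric choice,
    allocentric map placement, heading direction), Sea Hero Quest wayfinding
    and flare levels (turn-weighted star accuracy, worst-score imputation for
    non-completers), and a real-world detour navigation test on a street
    graph (wrong-turn detection with a two-consecutive-error reset, per-route
    disorientation scores, and a ratio composite with a +1 continuity
    correction) - and runs the downstream four-step group analysis:
    normality-gated two-sample comparisons with pooled-SD Cohen's d, ANCOVA
    with an inverse transform, standardized linear regression with Cohen's
    f-squared, and binomial logistic risk prediction. A synthetic-cohort
    generator with moment-matched truncated-normal score distributions and an
    event-level walk simulator make the whole pipeline testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
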