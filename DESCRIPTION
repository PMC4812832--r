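Package: habitr
Title: Life Logs, Behavior Clusters, and Exploit-Explore Activity and
    Food Suggestions from Mobile Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns raw mobile-phone sensor streams (tri-axial
    accelerometer plus GPS at 1 Hz) and manual food logs into concise
    chronological life logs, groups repeated behaviors into clusters
    (stationary places within 150 m, walking and running trajectories by
    shape, foods by ingredient similarity), scores clusters by aggregate
    weekly calorie impact (frequency times per-instance METS calories),
    and emits daily batches of 10 activity and 10 food suggestions under
    a fixed 90/10 exploit-explore multi-armed-bandit split, including
    small-change suggestions (a 3-minute walk per stationary hour).
    Ships a seeded synthetic-data generator for users and two-arm trials
    with known ground truth, and the trial statistics used to evaluate
    behavior change: weekly-median trend classification, exact Fisher
    2x2 tests by hypergeometric enumeration, exact and approximate
    Mann-Whitney U, pooled two-sample t with Cohen's d.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
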