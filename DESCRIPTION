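Package: forumdyn
Title: Session, Rhythm, Preference and Co-Consumption Analysis of Forum Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing timestamped user activity logs from online
    forums: segmentation of per-user event streams into sessions with an
    inactivity threshold, hour-of-week activity profiles with classification
    of circadian (24 h) and ultradian (12 h, 6 h) rhythms, k-means clustering
    of user category-preference vectors with elbow-based model selection and
    Shannon-entropy profiling, and a category co-consumption network weighted
    by relative risk with COPINE-based core-periphery segmentation. Includes
    a seeded synthetic event-log generator (archetype-structured preferences,
    heavy-tailed activity, planted rhythms, bursty session timing) so that
    every stage of the pipeline can be exercised and validated without access
    to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
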