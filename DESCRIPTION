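Package: ctsolver
Title: Cognitive Tangram Solver: Simulating and Anticipating Human Tangram Play
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid cognitive-model framework that simulates and anticipates human
    sequential problem solving in the Tangram puzzle. Visually afforded action-options
    are extracted from the uncovered silhouette by edge template matching (sum of
    squared differences), scored by a weighted combination of phase-conditioned
    behavioural frequencies and visual similarity, and selected through an
    activation-based memory retrieval model with a limited-capacity context buffer,
    retrieval noise, and two backtracking strategies (unfeasible-region and weakest-piece).
    Includes exact 45-degree polygon geometry for the puzzles, a synthetic participant
    trace generator with phase-structured errors, trace readers and writers, and four
    evaluation methods: overall step statistics, per-step choice heatmap RMSE,
    step-by-step state plausibility, and windowed next-action prediction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
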