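Package: mrscore
Title: Media Reporting Scorecard for Suicide-Related News
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens a newspaper corpus with PRISMA-style inclusion and
    exclusion accounting, codes each included article against a 20-item
    rubric of responsible suicide-reporting practices (10 protective, 10
    harmful criteria, each scored 1/0), either automatically via versioned
    keyword lexicons with evidence spans or by ingesting manual coding
    sheets, reconciles dual-coder output, and aggregates per-article scores
    into per-newspaper mean (SD) summaries, criterion frequency tables and
    period-over-period comparisons. Ships a seeded synthetic-corpus
    generator with per-criterion ground truth so every stage is testable
    without real news data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
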