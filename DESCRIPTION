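Package: nonwordvar
Title: Session-to-Session Variability in Nonword Reading Aloud
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how adults' pronunciations of nonwords vary
    across repeated testing sessions. Derives context-dependent
    grapheme-to-phoneme correspondence statistics and Shannon-entropy
    consistency scores from a syllabified phonemic lexicon, computes
    behavioural statistics from long-format response transcriptions
    (distinct-pronunciation counts, response diversity, novel-pronunciation
    coding, per-session Gower distances between readers, pronunciation
    frequency trajectories), fits the corresponding mixed-effects models
    with marginal and conditional R-squared, and simulates multi-session
    reader populations with a reinforcement ("settling") dynamic so that
    every stage of the pipeline can be tested without access to a licensed
    lexical database or raw behavioural data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    methods,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
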