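Package: mbsced
Title: Multiple-Baseline Single-Case Experimental Design Analysis for
    Parent-Child Interaction Therapy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing randomized, nonconcurrent multiple-baseline
    single-case experimental designs (SCEDs) of behavioral parent training,
    as used to evaluate Parent-Child Interaction Therapy (PCIT) with a
    virtual-reality practice add-on. Provides design randomization
    (baseline length and staggered add-on start), DPICS observation
    composites and mastery decisions, per-participant randomization tests
    with Monte-Carlo permutation nulls and Cohen's d effect sizes,
    group-level p-value combination via the exact Irwin-Hall (uniform-sum)
    distribution, Jacobson-Truax reliable change indices with clinical-range
    classification, paired nonparametric timepoint contrasts, and
    session-to-session skill-difference analyses conditioned on home
    practice. Includes a synthetic-data generator emulating weekly ECBI,
    OBVL-K and DPICS series with AR(1) noise, missingness and dropout, and
    an end-to-end reporting pipeline with plot-data export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
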