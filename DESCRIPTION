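Package: damsleep
Title: Sleep, Activity and Lifespan Analysis for Drosophila Activity
    Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for behavioural-ageing experiments that use
    Trikinetics-style Drosophila activity monitors (DAM). Parses per-beam
    monitor files, sums beams into per-tube activity, aligns recordings to
    the light schedule, scores sleep as runs of inactive minutes, computes
    per-fly activity totals, sleep amounts, sleep-bout counts and lengths,
    morning and evening anticipation indices, and applies a viability
    filter for flies that die during recording. Includes lifespan
    statistics (Kaplan-Meier curves, median lifespan, log-rank tests, Cox
    proportional-hazards models with interaction terms), group comparisons
    (two-way ANOVA, Dunnett many-to-one tests, Bonferroni adjustment), and
    a synthetic activity and lifespan generator with known ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    optparse,
    multcomp,
    mvtnorm,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
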