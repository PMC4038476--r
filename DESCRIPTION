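Package: touchzap
Title: Passive-Parameter Extraction and Event Detection for Touch-and-Zap
    Whole-Cell Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of in-vivo whole-cell current-clamp recordings obtained
    with the Touch-and-Zap access method. Provides an electrode-plus-cell
    equivalent-circuit simulator that synthesizes step-response sweeps and
    full approach-and-access session logs (seal formation, electroporation
    "zaps", resealing, suction); a heuristic passive-parameter extractor for
    resting potential, membrane time constant, residual access-resistance
    error and input resistance that discounts the fast electrode artifact;
    per-pulse resistance tracking with touch/zap/reseal/suction detection and
    endpoint classification (TZ, TZS, TS); neuron/glia classification with
    spike metrics and recording-quality rules; and cohort summaries with
    relative cell-size estimates, proportion tests, t tests and correlations.
    Traces and logs round-trip through documented plain-text TSV formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    jsonlite,
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
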