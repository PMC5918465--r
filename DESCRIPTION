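Package: survlamp
Title: Significant Combinatorial Survival Markers with Family-Wise Error
    Rate Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive detection of marker combinations (e.g. sets of
    jointly over-expressed genes) whose carriers show significantly
    different survival, assessed with the log-rank test while controlling
    the family-wise error rate. Multiple-testing correction follows the
    testability principle of Tarone and the Limitless Arity
    Multiple-testing Procedure (LAMP): a monotone lower bound on the
    minimum attainable log-rank p-value prunes combinations that can
    never reach significance, so the Bonferroni factor counts only
    testable combinations. Includes closed frequent itemset mining, the
    support-threshold search, chunked execution with aggregation of
    correction factors, readers for score/clinical tables, and a
    simulation module for null calibration and power studies on censored
    survival data.
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
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
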