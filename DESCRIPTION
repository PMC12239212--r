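Package: aneurescue
Title: Evolutionary Rescue of Tumors by Aneuploidy-Mediated Drug Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic and analytic models of tumor evolutionary rescue under
    anticancer drug treatment when chromosome missegregation produces aneuploid
    cells that are tolerant of, or partially resistant to, the drug. Implements
    a three-genotype (sensitive, aneuploid, resistant mutant) birth-death model
    with exact Gillespie simulation, tau-leaping, and a logistic
    density-dependent variant; multitype branching-process theory for rescue
    probabilities, threshold tumor sizes, and rescue, recurrence, and detection
    times; literature parameter presets for melanoma and triple-negative breast
    cancer; and reproducible figure-level experiments with bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
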